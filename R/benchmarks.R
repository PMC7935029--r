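# Frozen desk-scale benchmark experiments on the synthetic cohort. These are
# the package's reference experiments: the cohort parameters, architecture,
# and training protocol are fixed here so that results are comparable across
# machines and seeds (see the methods vignette for how each value was chosen).

#' Slice records into non-overlapping evaluation windows
#'
#' Turns each record into `n_windows` pseudo-records of `window` consecutive
#' frames. Used to evaluate occlusion saliency at a finer accuracy
#' granularity than one prediction per record.
#'
#' @param records list of [roi_ts()] records.
#' @param window frames per window.
#' @param n_windows windows taken from the start of each record.
#' @return A flat list of [roi_ts()] records.
#' @export
slice_into_windows <- function(records, window, n_windows) {
  if (any(vapply(records, function(r) nrow(r$signals), integer(1)) <
          window * n_windows))
    stop("records too short for ", n_windows, " windows of ", window, " frames")
  out <- vector("list", length(records) * n_windows)
  i <- 0L
  for (r in records) {
    for (w in seq_len(n_windows)) {
      rr <- r
      rr$signals <- r$signals[((w - 1) * window + 1):(w * window), , drop = FALSE]
      rr$session_id <- paste0(r$session_id, "_w", w)
      i <- i + 1L
      out[[i]] <- rr
    }
  }
  out
}

# session-based split: first session(s) train, last session test
.session_split <- function(records) {
  ses <- vapply(records, function(r) r$session_id, character(1))
  levels <- sort(unique(ses))
  if (length(levels) < 2) stop("need at least 2 sessions for a session split")
  test_ses <- levels[length(levels)]
  list(train = records[ses != test_ses], test = records[ses == test_ses])
}

#' Reference architecture and training protocol for the benchmarks
#'
#' @param n_classes number of output classes.
#' @param node_pool node-to-frame reduction (see [cgcn_config()]).
#' @param seed training seed.
#' @param max_epochs training epochs.
#' @return A list with `config` ([cgcn_config()]) and `train` ([train_config()]).
#' @export
benchmark_protocol <- function(n_classes, node_pool = "flatten", seed = 1L,
                               max_epochs = 12) {
  list(
    config = cgcn_config(n_conv_layers = 5,
                         features_per_layer = c(4, 4, 8, 8, 16),
                         temporal_head = "average_pool",
                         node_pool = node_pool,
                         n_classes = n_classes,
                         l2_lambda = 0.001),
    train = train_config(clip_length = 100, batch_size = 12,
                         max_epochs = max_epochs, initial_lr = 0.01,
                         lr_patience_epochs = 8, seed = as.integer(seed))
  )
}

#' Individual-identification benchmark on the synthetic cohort
#'
#' Generates the reference fingerprint cohort (20 subjects x 2 sessions,
#' 60 ROIs in 4 networks, 600 frames per session, fingerprint strength 0.5),
#' builds the k-NN graph from the session-1 records only, trains the cGCN on
#' session-1 clips (the last clip of each subject is held out for
#' validation), and evaluates subject identification on the session-2
#' records at several frame counts.
#'
#' @param seed integer seed controlling cohort, initialization, and training.
#' @param k neighbors per node for the connectivity graph (default 5, the
#'   paper's preferred setting).
#' @param graph_kind `"connectivity"` or `"random"` (the random-GCN control).
#' @param eval_frames frame counts evaluated on the test session.
#' @param max_epochs training epochs.
#' @return A list with `accuracy` (named by frame count), `train_result`,
#'   `graph`, and `test_records`.
#' @export
identification_benchmark <- function(seed, k = 5,
                                     graph_kind = c("connectivity", "random"),
                                     eval_frames = c(100, 30, 1),
                                     max_epochs = 12) {
  graph_kind <- match.arg(graph_kind)
  cohort <- generate_cohort(cohort_spec(seed = seed))
  records <- label_by_subject(cohort$records)
  split <- .session_split(records)
  graph <- if (graph_kind == "connectivity")
    build_knn_graph(group_fc_from_records(split$train), k)
  else
    build_random_graph(ncol(split$train[[1]]$signals), k, seed = seed)

  proto <- benchmark_protocol(n_classes = 20, node_pool = "flatten",
                              seed = seed, max_epochs = max_epochs)
  clips <- prepare_clips(split$train, proto$train$clip_length)
  cv <- .train_val_split(clips)
  levels <- sort(unique(vapply(cv$train, `[[`, character(1), "class_label")))
  model <- new_cgcn_model(proto$config, graph, levels, seed = seed)
  res <- train_model(model, cv$train, cv$val, proto$train)

  acc <- vapply(eval_frames, function(nf)
    evaluate(res$best_model, split$test, nf)$accuracy, numeric(1))
  names(acc) <- paste0("frames_", eval_frames)
  list(accuracy = acc, train_result = res, graph = graph,
       test_records = split$test)
}

#' Occlusion-saliency benchmark on a 2-class synthetic cohort
#'
#' Generates the reference 2-class cohort (group effect 0.15 on the
#' informative networks' within-network correlations, fingerprint strength
#' 0.1), trains a max-pooling cGCN on session-1 clips, and runs the
#' single-ROI occlusion scan on session-2 windows. Returns the saliency map
#' together with the planted ground truth, so the map can be scored against
#' the informative-ROI set.
#'
#' @param seed integer seed.
#' @param k neighbors per node.
#' @param window,n_windows evaluation windows per test record (see
#'   [slice_into_windows()]).
#' @param max_epochs training epochs.
#' @return A list with `map` (a `saliency_map`), `informative_rois`,
#'   `train_result`, and `test_accuracy` (full-window baseline).
#' @export
occlusion_benchmark <- function(seed, k = 5, window = 30, n_windows = 6,
                                max_epochs = 10) {
  cohort <- generate_cohort(cohort_spec(n_classes = 2, group_effect = 0.15,
                                        fingerprint_strength = 0.1,
                                        seed = seed))
  split <- .session_split(cohort$records)
  graph <- build_knn_graph(group_fc_from_records(split$train), k)
  proto <- benchmark_protocol(n_classes = 2, node_pool = "max",
                              seed = seed, max_epochs = max_epochs)
  clips <- prepare_clips(split$train, proto$train$clip_length)
  cv <- .train_val_split(clips)
  levels <- sort(unique(vapply(cv$train, `[[`, character(1), "class_label")))
  model <- new_cgcn_model(proto$config, graph, levels, seed = seed)
  res <- train_model(model, cv$train, cv$val, proto$train)
  windows <- slice_into_windows(split$test, window, n_windows)
  map <- occlusion_map(res$best_model, windows, window)
  list(map = map, informative_rois = cohort$truth$informative_rois,
       train_result = res,
       test_accuracy = map$baseline_accuracy)
}

#' Connectivity-versus-random-graph benchmark
#'
#' Runs [compare_graphs()] on the reference fingerprint cohort with the
#' benchmark protocol: graphs at the given k, both graph kinds, evaluated on
#' the held-out session in the few-frame regime (30 frames), where the
#' random-GCN deficit is largest.
#'
#' @param seeds integer vector of seeds (one matched pair of runs per seed).
#' @param k neighbors per node (default 3).
#' @param n_frames_eval test frames (default 30).
#' @param max_epochs training epochs.
#' @return The tidy results data.frame of [compare_graphs()].
#' @export
graph_comparison_benchmark <- function(seeds, k = 3, n_frames_eval = 30,
                                       max_epochs = 8) {
  cohort <- generate_cohort(cohort_spec(seed = seeds[1]))
  records <- label_by_subject(cohort$records)
  split <- .session_split(records)
  proto <- benchmark_protocol(n_classes = 20, node_pool = "flatten",
                              max_epochs = max_epochs)
  compare_graphs(split$train, split$test, k_values = k,
                 model_factory = cgcn_model_factory(proto$config),
                 train_cfg = proto$train, seeds = as.integer(seeds),
                 n_frames_eval = n_frames_eval)
}
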