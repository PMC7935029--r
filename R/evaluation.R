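#' Evaluate a model with a fixed number of test frames
#'
#' Each record is standardized over its full length, its first `n_frames`
#' frames form one test clip, and the predicted class is the argmax of the
#' class probabilities (first index on ties). `n_frames = 1` is legal:
#' frame-wise features make single-frame prediction possible.
#'
#' @param model a `cgcn_model` (anything with a `predict` method returning a
#'   probability matrix and a `class_levels` field).
#' @param records list of [roi_ts()] records, each with at least `n_frames`
#'   frames.
#' @param n_frames frames used from the start of each record.
#' @param zscore standardize each record before slicing (default TRUE).
#' @return An `eval_report`: `n_frames_used`, `accuracy`,
#'   `per_class_accuracy`, `n_records`, `predicted`, `truth`.
#' @export
evaluate <- function(model, records, n_frames, zscore = TRUE) {
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 1)
  short <- vapply(records, function(r) nrow(r$signals) < n_frames, logical(1))
  if (any(short))
    stop("record(s) shorter than n_frames = ", n_frames, ": ",
         paste(vapply(records[short], function(r)
       paste0(r$subject_id, "/", r$session_id), character(1)), collapse = ", "))
  clips <- lapply(records, function(r) {
    x <- if (zscore) zscore_signals(r$signals) else r$signals
    x[seq_len(n_frames), , drop = FALSE]
  })
  probs <- stats::predict(model, clips)
  pred <- model$class_levels[max.col(probs, ties.method = "first")]
  truth <- vapply(records, function(r) r$class_label, character(1))
  acc <- mean(pred == truth)
  per_class <- vapply(split(pred == truth, truth), mean, numeric(1))
  structure(list(n_frames_used = n_frames, accuracy = acc,
                 per_class_accuracy = per_class,
                 n_records = length(records),
                 predicted = pred, truth = truth),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d records @ %d frames: accuracy %.3f\n",
              x$n_records, x$n_frames_used, x$accuracy))
  invisible(x)
}

#' Default model factory
#'
#' Returns a function `(graph, class_levels, seed)` creating a fresh
#' `cgcn_model` from a shared base configuration; used by the CV and
#' graph-comparison harnesses.
#'
#' @param config a [cgcn_config()]; its `n_classes` is overridden per fold by
#'   the number of training classes.
#' @return A factory closure.
#' @export
cgcn_model_factory <- function(config = cgcn_config()) {
  force(config)
  function(graph, class_levels, seed) {
    cfg <- config
    cfg$n_classes <- length(class_levels)
    new_cgcn_model(cfg, graph, class_levels, seed = seed)
  }
}

# split clips into train/val deterministically: stratified by class, every
# ceil(1/frac)-th clip of each class goes to validation
.train_val_split <- function(clips, val_fraction = 0.25) {
  lab <- vapply(clips, function(cl) cl$class_label, character(1))
  val_idx <- unlist(lapply(split(seq_along(clips), lab), function(ix) {
    nv <- max(1L, floor(length(ix) * val_fraction))
    ix[seq(length(ix) - nv + 1L, length(ix))]
  }), use.names = FALSE)
  list(train = clips[-val_idx], val = clips[val_idx])
}

# one fold: build graph from training records ONLY, train, evaluate held-out
.run_fold <- function(train_records, test_records, model_factory, train_cfg,
                      k, n_frames_eval, seed, graph = NULL, verbose = FALSE) {
  if (is.null(graph)) {
    gfc <- group_fc_from_records(train_records)
    graph <- build_knn_graph(gfc, k)
  }
  train_clips_all <- prepare_clips(train_records, train_cfg$clip_length)
  split <- .train_val_split(train_clips_all)
  class_levels <- sort(unique(vapply(split$train, function(cl)
    cl$class_label, character(1))))
  if (length(class_levels) < 2)
    stop("training subset contains fewer than 2 classes")
  model <- model_factory(graph, class_levels, seed)
  res <- train_model(model, split$train, split$val, train_cfg,
                     verbose = verbose)
  report <- evaluate(res$best_model, test_records, n_frames_eval)
  list(report = report, result = res, graph = graph)
}

.cv_report <- function(scheme, per_fold) {
  accs <- vapply(per_fold, function(r) r$accuracy, numeric(1))
  structure(list(scheme = scheme, per_fold = per_fold,
                 mean_accuracy = mean(accs), min_accuracy = min(accs),
                 max_accuracy = max(accs)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: %d folds, mean %.3f (min %.3f, max %.3f)\n",
              x$scheme, length(x$per_fold), x$mean_accuracy,
              x$min_accuracy, x$max_accuracy))
  invisible(x)
}

#' Leave-one-site-out cross-validation
#'
#' One fold per acquisition site: the fold's group FC matrix, k-NN graph, and
#' model weights are derived exclusively from the other sites' records; the
#' held-out site is only ever touched at evaluation time, so site-specific
#' variation is a true out-of-distribution test.
#'
#' @param records list of [roi_ts()] records spanning at least 2 sites.
#' @param model_factory `(graph, class_levels, seed)` factory, e.g.
#'   [cgcn_model_factory()].
#' @param train_cfg a [train_config()].
#' @param k neighbors for the fold graphs.
#' @param n_frames_eval frames used at test time.
#' @param verbose forwarded to [train_model()].
#' @return A `cv_report` with one `eval_report` per site.
#' @export
leave_one_site_out <- function(records, model_factory, train_cfg, k,
                               n_frames_eval, verbose = FALSE) {
  sites <- vapply(records, function(r) r$site_label, character(1))
  site_levels <- sort(unique(sites))
  if (length(site_levels) < 2) stop("need at least 2 sites")
  per_fold <- list()
  for (s in site_levels) {
    train_records <- records[sites != s]
    test_records <- records[sites == s]
    cls <- unique(vapply(train_records, function(r) r$class_label, character(1)))
    if (length(cls) < 2)
      stop("holding out site ", s, " leaves fewer than 2 classes in training")
    fold <- .run_fold(train_records, test_records, model_factory, train_cfg,
                      k, n_frames_eval, seed = train_cfg$seed,
                      verbose = verbose)
    per_fold[[s]] <- fold$report
  }
  .cv_report("leave_one_site_out", per_fold)
}

#' Stratified subject-level fold assignment
#'
#' Partitions subjects into `n_folds` folds preserving the (site x class)
#' proportions as closely as integer counts allow: within each stratum the
#' subjects are shuffled and dealt round-robin, with the dealing origin
#' rotating across strata to balance fold sizes. All sessions of a subject
#' share its fold.
#'
#' @param records list of [roi_ts()] records.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed; the partition is reproducible from it.
#' @return Named integer vector: fold id per subject id.
#' @export
stratified_subject_folds <- function(records, n_folds, seed) {
  stopifnot(n_folds >= 2)
  subj <- vapply(records, function(r) r$subject_id, character(1))
  info <- unique(data.frame(
    subject = subj,
    site = vapply(records, function(r) r$site_label, character(1)),
    class = vapply(records, function(r) r$class_label, character(1)),
    stringsAsFactors = FALSE))
  if (anyDuplicated(info$subject))
    stop("subject(s) with inconsistent site/class metadata across sessions")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  strata <- split(info$subject, paste(info$site, info$class, sep = "\r"))
  small <- vapply(strata, length, integer(1)) < n_folds
  if (any(small))
    stop("n_folds = ", n_folds, " exceeds the size of the smallest ",
         "(site x class) stratum (", min(lengths(strata)), " subjects)")
  fold_of <- integer(0)
  origin <- 0L
  for (st in strata) {
    st <- sample(st)
    folds <- ((origin + seq_along(st) - 1L) %% n_folds) + 1L
    fold_of[st] <- folds
    origin <- (origin + length(st)) %% n_folds
  }
  fold_of
}

#' Stratified k-fold cross-validation
#'
#' Subjects (not clips) are partitioned with [stratified_subject_folds()], so
#' no subject's sessions ever straddle the train/test boundary. Each fold's
#' graph and weights are rebuilt from its training records only.
#'
#' @param records list of [roi_ts()] records.
#' @param n_folds number of folds.
#' @param model_factory,train_cfg,k,n_frames_eval,verbose as in
#'   [leave_one_site_out()].
#' @param seed seed for the partition.
#' @return A `cv_report` with one `eval_report` per fold.
#' @export
stratified_kfold <- function(records, n_folds, model_factory, train_cfg, k,
                             n_frames_eval, seed = train_cfg$seed,
                             verbose = FALSE) {
  fold_of <- stratified_subject_folds(records, n_folds, seed)
  subj <- vapply(records, function(r) r$subject_id, character(1))
  rec_fold <- fold_of[subj]
  per_fold <- list()
  for (f in sort(unique(rec_fold))) {
    train_records <- records[rec_fold != f]
    test_records <- records[rec_fold == f]
    if (length(test_records) == 0) next
    fold <- .run_fold(train_records, test_records, model_factory, train_cfg,
                      k, n_frames_eval, seed = train_cfg$seed,
                      verbose = verbose)
    per_fold[[paste0("fold", f)]] <- fold$report
  }
  .cv_report("stratified_kfold", per_fold)
}

#' Compare connectivity graphs against random graphs
#'
#' Trains matched models that differ only in how the neighborhood graph is
#' built -- from the training records' group FC, or uniformly at random -- and
#' evaluates each on the held-out records. This is the random-GCN control:
#' if connectomic neighborhoods matter, the connectivity graph should win,
#' especially at small k.
#'
#' @param train_records,test_records record lists; graphs and weights are
#'   derived from `train_records` only.
#' @param k_values integer vector of neighborhood sizes.
#' @param graph_kinds subset of `c("connectivity", "random")`.
#' @param model_factory,train_cfg as in [leave_one_site_out()].
#' @param seeds integer vector; each seed reinitializes weights (and the
#'   random graph).
#' @param n_frames_eval frames used at test time.
#' @param verbose forwarded to [train_model()].
#' @return A data.frame with columns `graph_kind`, `k`, `seed`, `accuracy`
#'   (one row per combination).
#' @export
compare_graphs <- function(train_records, test_records, k_values,
                           graph_kinds = c("connectivity", "random"),
                           model_factory = cgcn_model_factory(),
                           train_cfg = train_config(),
                           seeds = 1L, n_frames_eval = 30L,
                           verbose = FALSE) {
  graph_kinds <- match.arg(graph_kinds, several.ok = TRUE)
  gfc <- group_fc_from_records(train_records)
  n <- ncol(gfc$values)
  rows <- list()
  for (k in k_values) {
    conn_graph <- if ("connectivity" %in% graph_kinds)
      build_knn_graph(gfc, k) else NULL
    for (kind in graph_kinds) {
      for (seed in seeds) {
        graph <- if (kind == "connectivity") conn_graph
          else build_random_graph(n, k, seed = seed)
        cfg <- train_cfg
        cfg$seed <- as.integer(seed)
        fold <- .run_fold(train_records, test_records, model_factory, cfg,
                          k, n_frames_eval, seed = seed, graph = graph,
                          verbose = verbose)
        rows[[length(rows) + 1L]] <- data.frame(
          graph_kind = kind, k = as.integer(k), seed = as.integer(seed),
          accuracy = fold$report$accuracy)
      }
    }
  }
  do.call(rbind, rows)
}
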