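#' Training protocol configuration
#'
#' Adam with stepwise learning-rate decay (the rate is multiplied by
#' `lr_decay_factor` whenever validation accuracy has not improved for
#' `lr_patience_epochs` epochs, floored at `min_lr`), cross-entropy plus L2
#' penalty, and best-validation checkpointing: parameters are snapshotted only
#' when a new best validation accuracy is reached.
#'
#' @param clip_length frames per training clip (default 100).
#' @param batch_size clips per minibatch.
#' @param max_epochs training epochs.
#' @param initial_lr initial Adam learning rate.
#' @param lr_decay_factor multiplicative decay in (0, 1).
#' @param lr_patience_epochs epochs without validation improvement before a
#'   decay step.
#' @param min_lr learning-rate floor (default 1e-6).
#' @param l2_grid L2 coefficients swept by [l2_sweep()]
#'   (default 0.1, 0.01, 0.001, 0.0001).
#' @param grad_clip global-norm gradient clipping threshold (Inf disables).
#' @param seed integer seed for shuffling (and the base for sweep offsets).
#' @return A `train_config` list.
#' @export
train_config <- function(clip_length = 100, batch_size = 16, max_epochs = 30,
                         initial_lr = 0.01, lr_decay_factor = 0.5,
                         lr_patience_epochs = 5, min_lr = 1e-6,
                         l2_grid = c(0.1, 0.01, 0.001, 0.0001),
                         grad_clip = 5, seed = 1L) {
  stopifnot(clip_length >= 1, batch_size >= 1, max_epochs >= 1,
            initial_lr > 0, lr_decay_factor > 0, lr_decay_factor < 1,
            lr_patience_epochs >= 1, min_lr > 0, min_lr <= initial_lr,
            length(l2_grid) >= 1, all(l2_grid >= 0), grad_clip > 0)
  structure(list(
    clip_length = as.integer(clip_length), batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), initial_lr = initial_lr,
    lr_decay_factor = lr_decay_factor,
    lr_patience_epochs = as.integer(lr_patience_epochs), min_lr = min_lr,
    l2_grid = l2_grid, grad_clip = grad_clip, seed = as.integer(seed)
  ), class = "train_config")
}

#' Cut a record into non-overlapping clips
#'
#' Consecutive windows of exactly `clip_length` frames in temporal order; a
#' trailing remainder shorter than `clip_length` is dropped. Each clip
#' inherits the record's labels.
#'
#' @param record an [roi_ts()] record.
#' @param clip_length frames per clip.
#' @param zscore standardize each ROI column over the whole record before
#'   cutting (default TRUE; see [zscore_signals()]).
#' @return List of clips, each a list with `x` (clip_length x N matrix),
#'   `class_label`, `subject_id`, `session_id`, `site_label`.
#' @export
make_clips <- function(record, clip_length, zscore = TRUE) {
  T_total <- nrow(record$signals)
  if (T_total < clip_length)
    stop("record ", record$subject_id, "/", record$session_id, " has ",
         T_total, " frames, fewer than clip_length = ", clip_length)
  x <- if (zscore) zscore_signals(record$signals) else record$signals
  n_clips <- T_total %/% clip_length
  lapply(seq_len(n_clips), function(i) {
    rows <- ((i - 1) * clip_length + 1):(i * clip_length)
    list(x = x[rows, , drop = FALSE],
         class_label = record$class_label,
         subject_id = record$subject_id,
         session_id = record$session_id,
         site_label = record$site_label)
  })
}

#' Cut many records into clips
#'
#' @param records list of [roi_ts()] records.
#' @param clip_length frames per clip.
#' @param zscore see [make_clips()].
#' @return A flat list of clips.
#' @export
prepare_clips <- function(records, clip_length, zscore = TRUE) {
  unlist(lapply(records, make_clips, clip_length = clip_length,
                zscore = zscore),
         recursive = FALSE)
}

# ---- Adam over the nested parameter tree ------------------------------------

.tree_zero_like <- function(p) {
  if (is.list(p)) lapply(p, .tree_zero_like)
  else array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
}

# in-place-style Adam step on nested lists; returns list(params, m, v)
.adam_step <- function(params, grads, m, v, lr, step,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  rec <- function(p, g, mm, vv) {
    if (is.list(p)) {
      out_p <- p; out_m <- mm; out_v <- vv
      for (i in seq_along(p)) {
        if (is.null(p[[i]])) next
        r <- rec(p[[i]], g[[i]], mm[[i]], vv[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      mm <- beta1 * mm + (1 - beta1) * g
      vv <- beta2 * vv + (1 - beta2) * g^2
      mhat <- mm / (1 - beta1^step)
      vhat <- vv / (1 - beta2^step)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
    }
  }
  rec(params, grads, m, v)
}

.tree_sumsq <- function(g) {
  if (is.list(g)) sum(vapply(g, function(x)
    if (is.null(x)) 0 else .tree_sumsq(x), numeric(1)))
  else sum(g^2)
}

.tree_scale <- function(g, s) {
  if (is.list(g)) lapply(g, function(x) if (is.null(x)) NULL else .tree_scale(x, s))
  else g * s
}

.clip_labels_to_idx <- function(clips, class_levels) {
  lab <- vapply(clips, function(cl) cl$class_label, character(1))
  idx <- match(lab, class_levels)
  if (anyNA(idx))
    stop("clip labels not in model class_levels: ",
         paste(unique(lab[is.na(idx)]), collapse = ", "))
  idx
}

.batch_accuracy <- function(model, clips, y_idx, batch_size = 64L) {
  n <- length(clips)
  Tlen <- nrow(clips[[1]]$x)
  correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    fw <- .cgcn_batch_forward(model,
                              .stack_clips(lapply(clips[sel], `[[`, "x")),
                              length(sel), Tlen)
    pred <- max.col(fw$probs, ties.method = "first")
    correct <- correct + sum(pred == y_idx[sel])
  }
  correct / n
}

#' Train a cGCN model
#'
#' Minimizes cross-entropy plus `l2_lambda * sum(W^2)` with Adam. After each
#' epoch the model is evaluated on the validation clips; the learning rate is
#' multiplied by `lr_decay_factor` when validation accuracy has not improved
#' for `lr_patience_epochs` epochs (never below `min_lr`), and parameters are
#' snapshotted only when a new best validation accuracy is reached. The
#' returned model carries the best snapshot.
#'
#' @param model a fresh [new_cgcn_model()].
#' @param train_clips,val_clips non-empty clip lists from [prepare_clips()];
#'   every validation label must occur among the model's class levels.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return A `train_result`: `best_model`, `best_val_accuracy`, `history`
#'   (data.frame: epoch, loss, train_acc, val_acc, lr), `chosen_l2`.
#' @export
train_model <- function(model, train_clips, val_clips, cfg, verbose = FALSE) {
  if (length(train_clips) == 0 || length(val_clips) == 0)
    stop("train and validation clip sets must be non-empty")
  y_train <- .clip_labels_to_idx(train_clips, model$class_levels)
  y_val <- .clip_labels_to_idx(val_clips, model$class_levels)
  Tlen <- nrow(train_clips[[1]]$x)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)

  m <- .tree_zero_like(model$params)
  v <- .tree_zero_like(model$params)
  lr <- cfg$initial_lr
  step <- 0L
  best_val <- -Inf
  best_params <- model$params
  best_bn_stats <- model$bn_stats
  since_improve <- 0L
  n <- length(train_clips)
  hist <- vector("list", cfg$max_epochs)

  # pre-stack clips once; a batch is a column subset
  stacked <- vapply(train_clips, function(cl) as.vector(t(cl$x)),
                    numeric(Tlen * ncol(train_clips[[1]]$x)))

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      sel <- ord[start:min(start + cfg$batch_size - 1L, n)]
      H0 <- matrix(as.vector(stacked[, sel]), ncol = 1)
      lg <- .cgcn_loss_and_grads(model, H0, y_train[sel], length(sel), Tlen)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch,
             " (lr = ", lr, "); aborting")
      gnorm <- sqrt(.tree_sumsq(lg$grads))
      if (is.finite(cfg$grad_clip) && gnorm > cfg$grad_clip)
        lg$grads <- .tree_scale(lg$grads, cfg$grad_clip / gnorm)
      step <- step + 1L
      upd <- .adam_step(model$params, lg$grads, m, v, lr, step)
      model$params <- upd$p; m <- upd$m; v <- upd$v
      model$bn_stats <- lg$new_bn_stats
      losses <- c(losses, lg$loss)
      pred <- max.col(lg$probs, ties.method = "first")
      correct <- correct + sum(pred == y_train[sel])
    }
    train_acc <- correct / n
    val_acc <- .batch_accuracy(model, val_clips, y_val)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                train_acc = train_acc, val_acc = val_acc,
                                lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train %.3f  val %.3f  lr %.2g",
                      epoch, mean(losses), train_acc, val_acc, lr))
    if (val_acc > best_val) {
      best_val <- val_acc
      best_params <- model$params
      best_bn_stats <- model$bn_stats
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= cfg$lr_patience_epochs) {
        lr <- max(lr * cfg$lr_decay_factor, cfg$min_lr)
        since_improve <- 0L
      }
    }
  }

  best_model <- model
  best_model$params <- best_params
  best_model$bn_stats <- best_bn_stats
  structure(list(best_model = best_model, best_val_accuracy = best_val,
                 history = do.call(rbind, hist),
                 chosen_l2 = model$config$l2_lambda),
            class = "train_result")
}

#' Sweep the L2 regularization grid
#'
#' Runs [train_model()] once per value of `cfg$l2_grid` with a fresh
#' initialization (seed offset by the grid position) and returns the run with
#' the highest best validation accuracy; ties go to the smaller L2 value.
#'
#' @param model_factory function `(l2_lambda, seed)` returning a fresh
#'   `cgcn_model` with that penalty.
#' @param train_clips,val_clips as in [train_model()].
#' @param cfg a [train_config()].
#' @param verbose forwarded to [train_model()].
#' @return The winning `train_result` (its `chosen_l2` is the selected value).
#' @export
l2_sweep <- function(model_factory, train_clips, val_clips, cfg,
                     verbose = FALSE) {
  grid <- sort(cfg$l2_grid)   # ascending, so ties keep the smaller value
  results <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    mod <- model_factory(grid[i], cfg$seed + i - 1L)
    run_cfg <- cfg
    run_cfg$seed <- cfg$seed + i - 1L
    results[[i]] <- train_model(mod, train_clips, val_clips, run_cfg,
                                verbose = verbose)
  }
  accs <- vapply(results, function(r) r$best_val_accuracy, numeric(1))
  results[[which.max(accs)]]  # which.max takes the first (smallest l2) on ties
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding the config, the graph, the
#' class levels, and every parameter array under stable names; reloading
#' reproduces forward outputs exactly on the same platform.
#'
#' @param model a `cgcn_model` (or a `train_result`, whose best model is
#'   saved).
#' @param path file path.
#' @return `load_checkpoint` returns the `cgcn_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "train_result")) model <- model$best_model
  stopifnot(inherits(model, "cgcn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cgcn_model"))
  model
}
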