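#' Zero out one ROI of a clip
#'
#' Returns a copy of the clip with the given ROI column set to zero in every
#' frame; all other entries are untouched. Because occlusion is applied after
#' per-record z-scoring, "zero" is the ROI's mean level.
#'
#' @param clip T x N numeric matrix.
#' @param roi ROI (column) index, 1 <= roi <= N.
#' @return The occluded T x N matrix.
#' @export
occlude_roi <- function(clip, roi) {
  roi <- as.integer(roi)
  if (roi < 1 || roi > ncol(clip))
    stop("roi index ", roi, " out of range 1..", ncol(clip))
  clip[, roi] <- 0
  clip
}

#' Single-ROI occlusion saliency
#'
#' Measures each ROI's contribution to classification: with the trained model
#' fixed, one ROI at a time is zeroed out in every test clip (after
#' z-scoring), and the drop in accuracy relative to the unoccluded baseline
#' is that ROI's saliency. The scan costs exactly N + 1 evaluation passes and
#' never alters the graph or the weights.
#'
#' @param model a trained `cgcn_model`.
#' @param records list of [roi_ts()] test records.
#' @param n_frames frames used from each record (as in [evaluate()]).
#' @return A `saliency_map`: `baseline_accuracy`, `per_roi_drop` (length-N
#'   vector of baseline minus occluded accuracy), `n_records`.
#' @export
occlusion_map <- function(model, records, n_frames) {
  n <- ncol(records[[1]]$signals)
  if (!is.null(model$graph) && model$graph$n_nodes != n)
    stop("records have ", n, " ROIs but the model's graph has ",
         model$graph$n_nodes, " nodes")
  clips <- lapply(records, function(r) {
    x <- zscore_signals(r$signals)
    if (nrow(x) < n_frames)
      stop("record ", r$subject_id, "/", r$session_id,
           " shorter than n_frames = ", n_frames)
    x[seq_len(n_frames), , drop = FALSE]
  })
  truth <- vapply(records, function(r) r$class_label, character(1))
  acc_of <- function(cls) {
    probs <- stats::predict(model, cls)
    mean(model$class_levels[max.col(probs, ties.method = "first")] == truth)
  }
  baseline <- acc_of(clips)
  drops <- vapply(seq_len(n), function(r)
    baseline - acc_of(lapply(clips, occlude_roi, roi = r)), numeric(1))
  structure(list(baseline_accuracy = baseline, per_roi_drop = drops,
                 n_records = length(records)),
            class = "saliency_map")
}

#' Average saliency maps
#'
#' Entrywise mean of the per-ROI accuracy drops across maps (e.g. one map per
#' cross-validation fold); the baseline is the mean baseline and `n_records`
#' the total.
#'
#' @param maps non-empty list of `saliency_map` objects with a common N.
#' @return A `saliency_map`.
#' @export
average_saliency <- function(maps) {
  if (length(maps) == 0) stop("empty list of saliency maps")
  ns <- vapply(maps, function(m) length(m$per_roi_drop), integer(1))
  if (length(unique(ns)) != 1)
    stop("saliency map dimension mismatch: ", paste(unique(ns), collapse = " vs "))
  drops <- Reduce(`+`, lapply(maps, function(m) m$per_roi_drop)) / length(maps)
  structure(list(
    baseline_accuracy = mean(vapply(maps, function(m) m$baseline_accuracy,
                                    numeric(1))),
    per_roi_drop = drops,
    n_records = sum(vapply(maps, function(m) m$n_records, integer(1)))
  ), class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  top <- order(x$per_roi_drop, decreasing = TRUE)[seq_len(min(5, length(x$per_roi_drop)))]
  cat(sprintf("<saliency_map> baseline %.3f over %d records; top ROIs: %s\n",
              x$baseline_accuracy, x$n_records,
              paste(sprintf("%d (%.3f)", top, x$per_roi_drop[top]),
                    collapse = ", ")))
  invisible(x)
}
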