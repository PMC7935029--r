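#' Per-record z-scoring of ROI columns
#'
#' Standardizes each ROI column of a record to mean 0 and unit standard
#' deviation over its frames. Correlation is scale-free, so the FC matrix is
#' unchanged, but the network consumes normalized magnitudes and per-site
#' gain/offset distortions are removed.
#'
#' @param signals T x N numeric matrix.
#' @return A T x N matrix with standardized columns.
#' @export
zscore_signals <- function(signals) {
  mu <- colMeans(signals)
  sdv <- apply(signals, 2, stats::sd)
  if (any(sdv == 0))
    stop("constant ROI column(s): ", paste(which(sdv == 0), collapse = ", "))
  sweep(sweep(signals, 2, mu, "-"), 2, sdv, "/")
}

#' Functional connectivity of one record
#'
#' Entry (a, b) is the Pearson correlation between the time courses of ROI a
#' and ROI b over all frames of the record.
#'
#' @param record an [roi_ts()] record or a plain T x N matrix.
#' @return An `fc_matrix`: list of `values` (N x N, symmetric, unit diagonal)
#'   and `n_records_averaged = 1`.
#' @export
compute_fc <- function(record) {
  signals <- if (inherits(record, "roi_ts")) record$signals else as.matrix(record)
  sdv <- apply(signals, 2, stats::sd)
  if (any(sdv == 0))
    stop("cannot compute FC: constant ROI column(s) ",
         paste(which(sdv == 0), collapse = ", "))
  vals <- stats::cor(signals)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  structure(list(values = vals, n_records_averaged = 1L), class = "fc_matrix")
}

#' Group-average functional connectivity
#'
#' Entrywise arithmetic mean of individual FC matrices (the group FC used for
#' graph construction). Averaging is on the raw correlation coefficients by
#' default; `fisher_z = TRUE` averages Fisher z-transformed values and
#' back-transforms.
#'
#' @param matrices non-empty list of `fc_matrix` objects with a common N.
#' @param fisher_z average in Fisher z space instead of raw r space.
#' @return An `fc_matrix` with `n_records_averaged` equal to the sum of the
#'   inputs' counts.
#' @export
group_fc <- function(matrices, fisher_z = FALSE) {
  if (length(matrices) == 0) stop("empty list of FC matrices")
  dims <- vapply(matrices, function(m) ncol(m$values), integer(1))
  if (length(unique(dims)) != 1)
    stop("FC dimension mismatch: ", paste(unique(dims), collapse = " vs "))
  arrs <- lapply(matrices, function(m) m$values)
  if (fisher_z) {
    zs <- lapply(arrs, function(a) atanh(pmin(pmax(a, -0.999999), 0.999999)))
    avg <- tanh(Reduce(`+`, zs) / length(zs))
  } else {
    avg <- Reduce(`+`, arrs) / length(arrs)
  }
  avg <- (avg + t(avg)) / 2
  diag(avg) <- 1
  structure(list(
    values = avg,
    n_records_averaged = sum(vapply(matrices, function(m) m$n_records_averaged, integer(1)))
  ), class = "fc_matrix")
}

#' Group FC straight from records
#'
#' Convenience wrapper: per-record FC matrices averaged with [group_fc()].
#'
#' @param records list of [roi_ts()] records.
#' @param fisher_z see [group_fc()].
#' @return An `fc_matrix`.
#' @export
group_fc_from_records <- function(records, fisher_z = FALSE) {
  group_fc(lapply(records, compute_fc), fisher_z = fisher_z)
}

#' k-nearest-neighbor connectivity graph
#'
#' For each node i, keeps directed edges to the k nodes j != i with the
#' largest signed correlation fc(i, j), sorted descending; ties are broken
#' toward the lower node index. The diagonal (self-correlation) is excluded,
#' so the graph has no self-loops. The graph is directed: (i, j) being an
#' edge does not imply (j, i) is.
#'
#' @param fc an `fc_matrix` or plain symmetric N x N matrix.
#' @param k neighbors per node, 1 <= k <= N - 1.
#' @return A `knn_graph`: list of `n_nodes`, `k`, `neighbors` (N x k integer
#'   matrix, row i = ordered out-neighbors of node i), `edge_values` (N x k
#'   matrix of the corresponding fc entries), and `kind = "connectivity"`.
#' @export
build_knn_graph <- function(fc, k) {
  vals <- if (inherits(fc, "fc_matrix")) fc$values else as.matrix(fc)
  n <- ncol(vals)
  k <- as.integer(k)
  if (k < 1 || k > n - 1)
    stop("k must be between 1 and N-1 = ", n - 1, " (got ", k, ")")
  neighbors <- matrix(0L, n, k)
  edge_values <- matrix(0, n, k)
  for (i in seq_len(n)) {
    row <- vals[i, ]
    row[i] <- -Inf
    ord <- order(-row, seq_along(row))[seq_len(k)]
    neighbors[i, ] <- ord
    edge_values[i, ] <- vals[i, ord]
  }
  structure(list(n_nodes = n, k = k, neighbors = neighbors,
                 edge_values = edge_values, kind = "connectivity"),
            class = "knn_graph")
}

#' Random control graph
#'
#' Each node receives k distinct neighbors drawn uniformly without
#' replacement from the other N - 1 nodes. Used as the random-GCN control:
#' the same architecture run on a graph that carries no connectivity
#' information.
#'
#' @param n_nodes number of nodes N.
#' @param k neighbors per node, 1 <= k <= N - 1.
#' @param seed integer seed; the graph is reproducible from it.
#' @return A `knn_graph` with `kind = "random"` and `edge_values = NA`.
#' @export
build_random_graph <- function(n_nodes, k, seed) {
  n <- as.integer(n_nodes)
  k <- as.integer(k)
  if (k < 1 || k > n - 1)
    stop("k must be between 1 and N-1 = ", n - 1, " (got ", k, ")")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  neighbors <- t(vapply(seq_len(n), function(i)
    sample(setdiff(seq_len(n), i), k), integer(k)))
  if (k == 1) neighbors <- matrix(as.integer(neighbors), n, 1)
  structure(list(n_nodes = n, k = k, neighbors = neighbors,
                 edge_values = matrix(NA_real_, n, k), kind = "random"),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("<knn_graph> %s, %d nodes, k = %d (%d directed edges)\n",
              x$kind, x$n_nodes, x$k, x$n_nodes * x$k))
  invisible(x)
}
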