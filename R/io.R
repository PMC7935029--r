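# All tabular artifacts use one dialect: tab-delimited UTF-8, '.' decimal,
# 1-based indices. Time-series files are frames x ROIs with a header row of
# ROI labels (optional on read).

#' Write / read an ROI time-series matrix
#'
#' The file is a TSV, frames as rows, ROIs as columns, with a header row of
#' ROI labels. Reading a header-less numeric file labels ROIs `roi1..roiN`.
#' Metadata lives in the cohort manifest, not in the matrix file; it can be
#' supplied to `read_timeseries` directly.
#'
#' @param record an [roi_ts()] record.
#' @param path file path.
#' @return `read_timeseries` returns an [roi_ts()].
#' @export
write_timeseries <- function(record, path) {
  utils::write.table(
    format(record$signals, digits = 17, trim = TRUE, scientific = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = paste0("roi", seq_len(ncol(record$signals))))
  invisible(path)
}

#' @rdname write_timeseries
#' @param subject_id,session_id,class_label,site_label metadata attached to
#'   the returned record.
#' @export
read_timeseries <- function(path, subject_id = "unknown",
                            session_id = "unknown", class_label = "unknown",
                            site_label = "unknown") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty time-series file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop("ragged row in ", path, ": line ", bad, " has ", widths[bad],
         " fields, expected ", widths[1])
  }
  first <- suppressWarnings(as.numeric(cells[[1]]))
  has_header <- anyNA(first)
  data_lines <- if (has_header) cells[-1] else cells
  if (length(data_lines) == 0) stop("no data rows in ", path)
  mat <- matrix(NA_real_, length(data_lines), widths[1])
  for (i in seq_along(data_lines)) {
    row <- suppressWarnings(as.numeric(data_lines[[i]]))
    if (anyNA(row))
      stop("non-numeric cell in ", path, ": line ",
           i + as.integer(has_header))
    mat[i, ] <- row
  }
  colnames(mat) <- if (has_header) cells[[1]] else paste0("roi", seq_len(widths[1]))
  roi_ts(mat, subject_id, session_id, class_label, site_label)
}

#' Write / read a cohort
#'
#' One time-series TSV per record plus a `manifest.tsv` (record path, subject,
#' session, class, site, n_frames, n_rois).
#'
#' @param records list of [roi_ts()] records.
#' @param dir output directory (created if missing).
#' @return `read_cohort` returns the list of records.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    fname <- sprintf("%s_%s.tsv", r$subject_id, r$session_id)
    write_timeseries(r, file.path(dir, fname))
    rows[[i]] <- data.frame(record_path = fname, subject_id = r$subject_id,
                            session_id = r$session_id,
                            class_label = r$class_label,
                            site_label = r$site_label,
                            n_frames = nrow(r$signals),
                            n_rois = ncol(r$signals))
  }
  utils::write.table(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("no manifest.tsv in ", dir)
  man <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                           colClasses = "character")
  if (length(unique(man$n_rois)) != 1)
    stop("manifest has inconsistent n_rois across records")
  lapply(seq_len(nrow(man)), function(i) {
    p <- file.path(dir, man$record_path[i])
    if (!file.exists(p)) stop("missing record file: ", p)
    read_timeseries(p, man$subject_id[i], man$session_id[i],
                    man$class_label[i], man$site_label[i])
  })
}

#' Write / read an FC matrix as square TSV
#'
#' @param fc an `fc_matrix`.
#' @param path file path.
#' @export
write_fc_matrix <- function(fc, path) {
  vals <- if (inherits(fc, "fc_matrix")) fc$values else as.matrix(fc)
  utils::write.table(format(vals, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = paste0("roi", seq_len(ncol(vals))))
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  dimnames(mat) <- NULL
  structure(list(values = mat, n_records_averaged = 1L), class = "fc_matrix")
}

#' Write / read a graph as an edge list
#'
#' TSV with header, one row per directed edge: `source`, `target`, `rank`
#' (1 = strongest neighbor), `fc_value` (NA for random graphs).
#'
#' @param graph a `knn_graph`.
#' @param path file path.
#' @export
write_edge_list <- function(graph, path) {
  n <- graph$n_nodes
  k <- graph$k
  df <- data.frame(source = rep(seq_len(n), each = k),
                   target = as.vector(t(graph$neighbors)),
                   rank = rep(seq_len(k), n),
                   fc_value = as.vector(t(graph$edge_values)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param kind graph kind recorded on read.
#' @export
read_edge_list <- function(path, kind = "connectivity") {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  n <- max(df$source)
  k <- max(df$rank)
  df <- df[order(df$source, df$rank), ]
  structure(list(n_nodes = as.integer(n), k = as.integer(k),
                 neighbors = matrix(as.integer(df$target), n, k, byrow = TRUE),
                 edge_values = matrix(df$fc_value, n, k, byrow = TRUE),
                 kind = kind),
            class = "knn_graph")
}

#' Write a saliency map as TSV
#'
#' Columns `roi_index`, `roi_label`, `accuracy_drop`, sorted by drop
#' descending.
#'
#' @param map a `saliency_map`.
#' @param path file path.
#' @param roi_labels optional character labels (default `roi<i>`).
#' @export
write_saliency <- function(map, path, roi_labels = NULL) {
  n <- length(map$per_roi_drop)
  if (is.null(roi_labels)) roi_labels <- paste0("roi", seq_len(n))
  ord <- order(map$per_roi_drop, decreasing = TRUE)
  df <- data.frame(roi_index = ord, roi_label = roi_labels[ord],
                   accuracy_drop = map$per_roi_drop[ord])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flat key-value config files
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numeric when possible, comma-separated values as vectors.
#'
#' @param config named list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(nm)
    paste0(nm, " = ", paste(config[[nm]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: ", ln)
    key <- trimws(parts[1])
    vals <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (anyNA(num)) vals else num
  }
  out
}
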