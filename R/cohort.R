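#' Specify a synthetic rs-fMRI cohort
#'
#' Describes a multi-subject, multi-session cohort of ROI-level BOLD-like time
#' series with planted structure at three levels: a shared block (network)
#' covariance, stable subject-specific connectivity fingerprints, and optional
#' class-dependent (diagnosis-like) connectivity differences, plus optional
#' per-site affine signal distortions. The defaults describe the cohort used
#' throughout the package's benchmarks: 20 subjects, 2 sessions each, 60 ROIs
#' in 4 networks.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions_per_subject sessions (independent scans) per subject.
#' @param n_rois number of ROIs (graph nodes) N.
#' @param n_frames frames (time points) T per session.
#' @param n_networks number of covariance blocks (resting-state networks).
#' @param within_network_corr baseline Pearson correlation between two ROIs of
#'   the same network, strictly in (0, 1).
#' @param between_network_corr baseline correlation across networks.
#' @param fingerprint_strength standard deviation of the additive symmetric
#'   perturbation of the correlation matrix that is unique to each subject and
#'   identical across that subject's sessions; 0 disables fingerprints.
#' @param group_effect magnitude of the class-dependent shift applied to the
#'   within-network correlations of the informative networks (opposite
#'   directions per class); 0 disables group differences.
#' @param n_classes number of diagnostic classes (subjects are dealt to
#'   classes round-robin).
#' @param n_sites number of acquisition sites; each site applies a fixed gain
#'   and offset to the signal.
#' @param site_effect magnitude of the per-site gain/offset deviation;
#'   0 makes all sites identical.
#' @param noise_sd marginal standard deviation of the generated signals.
#' @param ar_coef optional AR(1) coefficient in [0, 1) for temporal smoothing
#'   of the latent innovations; 0 (default) gives temporally white frames.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, n_sessions_per_subject = 2,
                        n_rois = 60, n_frames = 600, n_networks = 4,
                        within_network_corr = 0.4, between_network_corr = 0.05,
                        fingerprint_strength = 0.5, group_effect = 0,
                        n_classes = 1, n_sites = 1, site_effect = 0,
                        noise_sd = 1, ar_coef = 0, seed = 1L) {
  stopifnot(
    n_subjects >= 1, n_sessions_per_subject >= 1, n_rois >= 1, n_frames >= 2,
    n_networks >= 1, n_networks <= n_rois,
    within_network_corr > 0, within_network_corr < 1,
    between_network_corr > -1, between_network_corr < 1,
    fingerprint_strength >= 0, group_effect >= 0,
    n_classes >= 1, n_sites >= 1, site_effect >= 0,
    noise_sd > 0, ar_coef >= 0, ar_coef < 1
  )
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_sessions_per_subject = as.integer(n_sessions_per_subject),
    n_rois = as.integer(n_rois), n_frames = as.integer(n_frames),
    n_networks = as.integer(n_networks),
    within_network_corr = within_network_corr,
    between_network_corr = between_network_corr,
    fingerprint_strength = fingerprint_strength,
    group_effect = group_effect,
    n_classes = as.integer(n_classes), n_sites = as.integer(n_sites),
    site_effect = site_effect, noise_sd = noise_sd, ar_coef = ar_coef,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Construct an ROI time-series record
#'
#' @param signals T x N numeric matrix, frames as rows, ROIs as columns.
#' @param subject_id,session_id,class_label,site_label record metadata
#'   (coerced to character).
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(signals, subject_id, session_id, class_label, site_label = "site1") {
  signals <- as.matrix(signals)
  if (nrow(signals) < 2 || ncol(signals) < 2)
    stop("roi_ts needs at least 2 frames and 2 ROIs")
  if (anyNA(signals) || !all(is.finite(signals)))
    stop("roi_ts signals must be finite with no missing values")
  structure(list(
    subject_id = as.character(subject_id),
    session_id = as.character(session_id),
    class_label = as.character(class_label),
    site_label = as.character(site_label),
    signals = signals
  ), class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject=%s session=%s class=%s site=%s  [%d frames x %d ROIs]\n",
              x$subject_id, x$session_id, x$class_label, x$site_label,
              nrow(x$signals), ncol(x$signals)))
  invisible(x)
}

# Project a symmetric matrix to the nearest valid correlation matrix:
# clip eigenvalues at a small floor, then renormalize to unit diagonal.
project_to_correlation <- function(mat, eig_floor = 1e-4) {
  mat <- (mat + t(mat)) / 2
  eg <- eigen(mat, symmetric = TRUE)
  vals <- pmax(eg$values, eig_floor)
  out <- eg$vectors %*% (vals * t(eg$vectors))
  d <- sqrt(diag(out))
  if (any(d <= 0)) stop("covariance projection failed: non-positive diagonal")
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

# Block-structured base correlation matrix and network labels.
base_network_correlation <- function(n_rois, n_networks, within, between) {
  assign <- sort(rep_len(seq_len(n_networks), n_rois))
  same <- outer(assign, assign, "==")
  mat <- matrix(between, n_rois, n_rois)
  mat[same] <- within
  diag(mat) <- 1
  list(values = mat, network_assignment = assign)
}

#' Generate a synthetic cohort of ROI time series
#'
#' Draws each session as T i.i.d. (or AR(1)-smoothed) zero-mean multivariate
#' normal frames whose correlation matrix is the group block structure
#' perturbed by (a) the subject's fingerprint (a fixed random symmetric
#' perturbation over the informative ROIs, shared across that subject's
#' sessions) and (b) the subject's class effect (a fixed shift of the
#' informative networks' within-network entries, shared by all subjects of
#' the class); the result is projected back to a valid correlation matrix by
#' eigenvalue clipping.
#' Site membership applies a fixed per-site gain and offset to the signal.
#'
#' The informative ROIs -- the ones that carry fingerprint and class signal --
#' are the members of the first two networks (or of the single network when
#' `n_networks == 1`).
#'
#' @param spec a [cohort_spec()].
#' @return A list with `records` (list of [roi_ts()] objects, one per
#'   subject-session) and `truth`, a `cohort_truth` list holding
#'   `group_correlation`, `subject_correlations` (per subject-class-adjusted
#'   sampling correlation), `network_assignment`, `informative_rois`,
#'   `class_of_subject`, and `site_of_subject`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_frames < 2) stop("n_frames must be at least 2")
  N <- spec$n_rois
  base <- base_network_correlation(N, spec$n_networks,
                                   spec$within_network_corr,
                                   spec$between_network_corr)
  group_corr <- project_to_correlation(base$values)
  assign <- base$network_assignment

  inf_networks <- if (spec$n_networks >= 2) c(1L, 2L) else 1L
  informative <- which(assign %in% inf_networks)

  # class effect: within-network entries of the informative networks, shifted
  # in opposite directions per class (within-network alterations are carried
  # by the k-NN graph's edges, which concentrate inside networks)
  net_mask <- function(b) {
    m <- matrix(FALSE, N, N)
    m[assign == b, assign == b] <- TRUE
    diag(m) <- FALSE
    m
  }
  mask1 <- net_mask(inf_networks[1])
  mask2 <- if (length(inf_networks) >= 2) net_mask(inf_networks[2]) else mask1

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  class_of_subject <- rep_len(seq_len(spec$n_classes), spec$n_subjects)
  site_of_subject <- rep_len(rep(seq_len(spec$n_sites),
                                 each = max(1L, spec$n_classes)),
                             spec$n_subjects)

  # deterministic per-class direction on the two informative networks
  theta <- 2 * pi * (seq_len(spec$n_classes) - 1) / max(spec$n_classes, 2) + pi / 4
  class_dir1 <- cos(theta)
  class_dir2 <- sin(theta)

  site_gain <- 1 + spec$site_effect * stats::runif(spec$n_sites, -0.5, 0.5)
  site_offset <- spec$site_effect * stats::runif(spec$n_sites, -0.5, 0.5) * spec$noise_sd

  n_inf <- length(informative)
  subject_corr <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    pert <- matrix(0, N, N)
    if (spec$fingerprint_strength > 0 && n_inf >= 2) {
      block <- matrix(stats::rnorm(n_inf^2, sd = spec$fingerprint_strength), n_inf, n_inf)
      block <- (block + t(block)) / 2
      diag(block) <- 0
      pert[informative, informative] <- block
    }
    cl <- class_of_subject[s]
    if (spec$group_effect > 0) {
      pert[mask1] <- pert[mask1] + class_dir1[cl] * spec$group_effect
      pert[mask2] <- pert[mask2] + class_dir2[cl] * spec$group_effect
    }
    raw <- group_corr + pert
    diag(raw) <- 1
    raw[raw > 0.98] <- 0.98
    raw[raw < -0.98] <- -0.98
    diag(raw) <- 1
    subject_corr[[s]] <- project_to_correlation(raw)
  }

  records <- vector("list", spec$n_subjects * spec$n_sessions_per_subject)
  idx <- 1L
  for (s in seq_len(spec$n_subjects)) {
    ch <- chol(subject_corr[[s]])
    for (ses in seq_len(spec$n_sessions_per_subject)) {
      z <- matrix(stats::rnorm(spec$n_frames * N), spec$n_frames, N)
      if (spec$ar_coef > 0) {
        # AR(1) filter preserving unit marginal variance
        rho <- spec$ar_coef
        z <- apply(z, 2, function(col)
          as.numeric(stats::filter(col * sqrt(1 - rho^2), rho,
                                   method = "recursive")))
      }
      x <- spec$noise_sd * (z %*% ch)
      st <- site_of_subject[s]
      x <- x * site_gain[st] + site_offset[st]
      records[[idx]] <- roi_ts(
        signals = x,
        subject_id = sprintf("sub%03d", s),
        session_id = sprintf("ses%02d", ses),
        class_label = sprintf("class%d", class_of_subject[s]),
        site_label = sprintf("site%d", site_of_subject[s])
      )
      idx <- idx + 1L
    }
  }

  truth <- structure(list(
    group_correlation = group_corr,
    subject_correlations = subject_corr,
    network_assignment = assign,
    informative_rois = informative,
    class_of_subject = class_of_subject,
    site_of_subject = site_of_subject
  ), class = "cohort_truth")

  list(records = records, truth = truth)
}

#' Relabel records so that subject identity is the classification target
#'
#' Used for connectome-fingerprinting (individual identification) experiments,
#' where each subject is their own class.
#'
#' @param records list of [roi_ts()] records.
#' @return The records with `class_label` replaced by `subject_id`.
#' @export
label_by_subject <- function(records) {
  lapply(records, function(r) { r$class_label <- r$subject_id; r })
}

#' Within- versus between-subject fingerprint similarity
#'
#' Computes the functional-connectivity matrix of every record, vectorizes the
#' upper triangle, and reports the mean Pearson correlation between FC vectors
#' of same-subject session pairs versus different-subject pairs. A stable
#' connectome fingerprint shows `within > between`.
#'
#' @param records list of [roi_ts()] records; at least 2 subjects with at
#'   least 2 sessions each.
#' @return A list with `within_similarity` and `between_similarity`.
#' @export
cohort_fingerprint_check <- function(records) {
  subj <- vapply(records, function(r) r$subject_id, character(1))
  if (length(unique(subj)) < 2) stop("need at least 2 subjects")
  tab <- table(subj)
  if (any(tab < 2)) stop("every subject needs at least 2 sessions; offending: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  vecs <- vapply(records, function(r) {
    fc <- compute_fc(r)$values
    fc[upper.tri(fc)]
  }, numeric(sum(upper.tri(diag(ncol(records[[1]]$signals))))))
  n <- length(records)
  cors <- stats::cor(vecs)
  same <- outer(subj, subj, "==")
  ut <- upper.tri(cors)
  list(within_similarity = mean(cors[ut & same]),
       between_similarity = mean(cors[ut & !same]))
}
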