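#' Specify planted effects for synthetic connectivity
#'
#' The generative twin of the per-edge moderation GLM: every edge's
#' noiseless Fisher-z connectivity is
#' \deqn{z = \beta_0 + \beta_{age} age + \beta_{sex} sex + \beta_{grp} grp
#'       + \beta_{psqi} psqi + \beta_{int}\, grp \times psqi,}
#' with the interaction coefficient nonzero only on \code{affected_edges}.
#' Observation noise is i.i.d. Gaussian in Fisher-z space (the space in
#' which the GLM is fitted); an optional exchangeable correlation
#' \code{rho} across edges is available and defaults off.
#'
#' The default planted effect is a \emph{negative} interaction
#' (\code{beta_interaction = -0.03} z-units per PSQI point) with
#' \code{noise_sd = 0.15}: in the pain group the PSQI slope is pulled
#' downward, mirroring the dorsostriatal-sensorimotor moderation pattern
#' the package emulates.
#'
#' @param affected_edges integer matrix with two columns (ROI indices,
#'   1-based, row-wise pairs i < j) carrying the interaction effect.
#' @param beta_intercept,beta_age,beta_sex,beta_group,beta_psqi,beta_interaction
#'   GLM coefficients in Fisher-z units per covariate unit.
#' @param noise_sd standard deviation of the observation noise (z-units).
#' @param rho optional exchangeable noise correlation across edges, in
#'   \[0, 1).
#' @return An object of class \code{"effect_spec"}.
#' @seealso [simulate_fc()], [planted_network()]
#' @export
effect_spec <- function(affected_edges = planted_network()$edges,
                        beta_intercept = 0.25, beta_age = 0,
                        beta_sex = 0, beta_group = 0, beta_psqi = 0,
                        beta_interaction = -0.03,
                        noise_sd = 0.15, rho = 0) {
  affected_edges <- .as_edge_matrix(affected_edges)
  if (!.is_number(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!.is_prob(rho) || rho >= 1) stop("rho must lie in [0, 1)")
  betas <- c(intercept = beta_intercept, age = beta_age, sex = beta_sex,
             group = beta_group, psqi = beta_psqi,
             group_x_psqi = beta_interaction)
  if (!all(is.finite(betas))) stop("all betas must be finite")
  structure(list(affected_edges = affected_edges, betas = betas,
                 noise_sd = noise_sd, rho = rho),
            class = "effect_spec")
}

# Normalise edge input to a 2-column integer matrix with i < j rows.
.as_edge_matrix <- function(edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns (roi_i, roi_j)")
  storage.mode(edges) <- "integer"
  if (anyNA(edges) || any(edges < 1L)) stop("edge indices must be >= 1")
  if (any(edges[, 1] == edges[, 2])) stop("self-pairs are not allowed")
  swap <- edges[, 1] > edges[, 2]
  edges[swap, ] <- edges[swap, c(2, 1)]
  if (anyDuplicated(edges)) stop("duplicate edges")
  dimnames(edges) <- list(NULL, c("i", "j"))
  edges
}

#' Default planted ground-truth network
#'
#' A small six-edge network connecting two "striatal" stand-in ROIs to
#' four "sensorimotor" stand-ins, echoing the putamen/caudate-to-
#' precentral/postcentral moderation network the package emulates. Used as
#' the default \code{affected_edges} of [effect_spec()] and as the named
#' ground truth of the power and recovery suites.
#'
#' @param n_rois total ROI count of the synthetic atlas (>= 6); the
#'   planted nodes are always ROIs 1-6.
#' @return list with \code{edges} (6 x 2 integer matrix), \code{striatal}
#'   and \code{sensorimotor} (index vectors), and \code{labels} for the
#'   first six ROIs.
#' @export
planted_network <- function(n_rois = 20) {
  if (!.is_count(n_rois, 6L)) stop("n_rois must be a count >= 6")
  edges <- rbind(c(1L, 3L), c(1L, 4L), c(1L, 5L),
                 c(2L, 3L), c(2L, 4L), c(2L, 6L))
  dimnames(edges) <- list(NULL, c("i", "j"))
  list(edges = edges,
       striatal = 1:2, sensorimotor = 3:6,
       labels = c("Putamen L*", "Putamen R*", "Precentral gyrus L*",
                  "Precentral gyrus R*", "Postcentral gyrus L*",
                  "Postcentral gyrus R*"),
       n_rois = as.integer(n_rois))
}

#' Synthetic ROI set with sleep/pain stand-in roles
#'
#' A reduced-scale twin of the real atlas table that lets the standard
#' [build_edge_mask()] configurations run on synthetic data. The six
#' planted-network nodes (ROIs 1-6) are the sleep stand-ins - their real
#' counterparts (putamen, precentral and postcentral gyri) are all
#' sleep-flagged ROIs - and ROIs 7-8 are pain-only stand-ins (e.g.
#' thalamus-like), so the sleep-or-pain union has 8 ROIs. The remaining
#' ROIs are unflagged background. The S-SP analog mask over a 20-ROI
#' atlas therefore has 27 tested edges.
#'
#' @param n_rois synthetic atlas size (>= 8).
#' @return a \code{"roi_set"} data.frame, as from [load_roi_table()].
#' @export
synthetic_roi_set <- function(n_rois = 20) {
  if (!.is_count(n_rois, 8L)) stop("n_rois must be a count >= 8")
  pn <- planted_network(n_rois)
  tab <- data.frame(
    roi_id = seq_len(n_rois),
    name = .default_roi_labels(n_rois),
    hemisphere = rep(c("left", "right"), length.out = n_rois),
    is_sleep = as.integer(seq_len(n_rois) %in% 1:6),
    is_pain = as.integer(seq_len(n_rois) %in% c(1, 2, 5, 6, 7, 8)),
    stringsAsFactors = FALSE
  )
  tab$name[1:6] <- pn$labels
  tab$name[7:8] <- c("Thalamus L*", "Thalamus R*")
  structure(tab,
            n_sleep = sum(tab$is_sleep),
            n_pain = sum(tab$is_pain),
            n_union = sum(tab$is_sleep | tab$is_pain),
            class = c("roi_set", "data.frame"))
}

#' Simulate per-subject Fisher-z connectivity matrices
#'
#' Direct-FC generative mode: each subject's noiseless connectivity is the
#' effect-spec linear predictor evaluated at their covariates, and the
#' observed connectivity adds Gaussian noise in Fisher-z space,
#' independent across subjects (and across edges unless
#' \code{effects$rho > 0}).
#'
#' @param cohort a cohort table (see [simulate_cohort()]).
#' @param roi_count number of ROIs (>= 2).
#' @param effects an [effect_spec()].
#' @param seed integer seed.
#' @return An object of class \code{"synthetic_dataset"}: a list with
#'   \code{cohort}, \code{fc_truth} and \code{fc_observed} (ROI x ROI x
#'   subject arrays, symmetric, diagonal \code{NA}), and a
#'   \code{provenance} record of all parameters.
#' @examples
#' coh <- simulate_cohort(cohort_spec(seed = 1))
#' dat <- simulate_fc(coh, roi_count = 10, effect_spec(), seed = 2)
#' dim(dat$fc_observed)
#' @export
simulate_fc <- function(cohort, roi_count, effects = effect_spec(),
                        seed = 1L) {
  validate_cohort(cohort)
  if (!.is_count(roi_count, 2L)) stop("roi_count must be a count >= 2")
  if (!inherits(effects, "effect_spec")) stop("effects must be an effect_spec")
  if (any(effects$affected_edges > roi_count)) {
    stop("affected edge indices exceed roi_count")
  }
  n <- nrow(cohort)
  edges <- .all_pairs(roi_count)
  e_idx <- .edge_index(edges, roi_count)
  aff_idx <- .edge_index(effects$affected_edges, roi_count)
  b <- effects$betas

  # n x E matrix of noiseless edge values
  eta <- b["intercept"] + b["age"] * cohort$age + b["sex"] * cohort$sex +
    b["group"] * cohort$group + b["psqi"] * cohort$psqi
  truth <- matrix(eta, nrow = n, ncol = nrow(edges))
  aff_cols <- match(aff_idx, e_idx)
  if (length(aff_cols) > 0L) {
    truth[, aff_cols] <- truth[, aff_cols] +
      b["group_x_psqi"] * (cohort$group * cohort$psqi)
  }

  set.seed(seed)
  noise <- matrix(rnorm(n * nrow(edges), 0, effects$noise_sd),
                  nrow = n)
  if (effects$rho > 0 && effects$noise_sd > 0) {
    shared <- rnorm(n, 0, effects$noise_sd)
    noise <- sqrt(effects$rho) * shared +
      sqrt(1 - effects$rho) * noise
  }
  observed <- truth + noise

  labels <- .default_roi_labels(roi_count)
  fc_truth <- .edge_matrix_to_stack(truth, edges, roi_count, labels,
                                    cohort$subject_id)
  fc_observed <- .edge_matrix_to_stack(observed, edges, roi_count, labels,
                                       cohort$subject_id)
  structure(list(cohort = cohort, fc_truth = fc_truth,
                 fc_observed = fc_observed, timeseries = NULL,
                 provenance = list(mode = "fc", seed = as.integer(seed),
                                   roi_count = as.integer(roi_count),
                                   effects = effects)),
            class = "synthetic_dataset")
}

#' Simulate ROI time series with subject-specific target correlations
#'
#' Time-series generative mode: for every subject, draws
#' \code{n_timepoints} samples from a zero-mean Gaussian whose population
#' correlation matrix equals the subject's target (after projection to the
#' nearest positive-definite matrix by eigenvalue clipping at 1e-6 and
#' renormalisation to unit diagonal). Emulates a 10-minute resting-state
#' run: 300 time points at a sampling interval of 2 s.
#'
#' @param cohort a cohort table.
#' @param target_corr_builder function mapping one cohort row (a
#'   single-row data.frame) to a valid correlation matrix (symmetric, unit
#'   diagonal). See [fc_target_builder()] for the generative default.
#' @param n_timepoints samples per subject (default 300).
#' @param seed integer seed.
#' @param sampling_interval seconds between samples (default 2).
#' @return A \code{"synthetic_dataset"} whose \code{timeseries} element is
#'   a named list of time x ROI matrices and whose \code{fc_truth} stack
#'   holds the Fisher-z transform of each subject's target correlations.
#' @export
simulate_timeseries <- function(cohort, target_corr_builder,
                                n_timepoints = 300, seed = 1L,
                                sampling_interval = 2) {
  validate_cohort(cohort)
  if (!is.function(target_corr_builder)) {
    stop("target_corr_builder must be a function(cohort_row) -> matrix")
  }
  if (!.is_count(n_timepoints, 2L)) stop("n_timepoints must be a count >= 2")
  set.seed(seed)
  n <- nrow(cohort)
  ts_list <- vector("list", n)
  z_list <- vector("list", n)
  labels <- NULL
  for (s in seq_len(n)) {
    target <- target_corr_builder(cohort[s, , drop = FALSE])
    target <- .validate_corr_target(target, cohort$subject_id[s])
    if (is.null(labels)) {
      labels <- colnames(target)
      if (is.null(labels)) labels <- .default_roi_labels(ncol(target))
    }
    R <- .nearest_pd_corr(target)
    U <- chol(R)
    Z <- matrix(rnorm(n_timepoints * ncol(R)), nrow = n_timepoints)
    x <- Z %*% U
    colnames(x) <- labels
    attr(x, "sampling_interval") <- sampling_interval
    ts_list[[s]] <- x
    zt <- suppressWarnings(atanh(pmin(pmax(target, -1 + 1e-12),
                                      1 - 1e-12)))
    diag(zt) <- NA_real_
    z_list[[s]] <- zt
  }
  names(ts_list) <- cohort$subject_id
  p <- length(labels)
  fc_truth <- array(unlist(z_list), dim = c(p, p, n),
                    dimnames = list(labels, labels, cohort$subject_id))
  structure(list(cohort = cohort, fc_truth = fc_truth,
                 fc_observed = NULL, timeseries = ts_list,
                 provenance = list(mode = "timeseries",
                                   seed = as.integer(seed),
                                   n_timepoints = as.integer(n_timepoints),
                                   sampling_interval = sampling_interval)),
            class = "synthetic_dataset")
}

#' Build a generative target-correlation rule from an effect spec
#'
#' Returns a function mapping a cohort row to a correlation matrix whose
#' off-diagonal entries are \code{tanh} of the effect-spec linear
#' predictor, i.e. the time-series twin of [simulate_fc()]: feeding the
#' simulated series through [compute_fc_matrix()] and the per-edge GLM
#' recovers the planted coefficients up to correlation sampling noise.
#'
#' @param roi_count atlas size of the synthetic subject.
#' @param effects an [effect_spec()]; \code{noise_sd} and \code{rho} are
#'   ignored here (sampling noise comes from the finite time series).
#' @param baseline background Fisher-z value of unaffected edges.
#' @return function(cohort_row) -> correlation matrix.
#' @export
fc_target_builder <- function(roi_count, effects = effect_spec(),
                              baseline = 0.1) {
  force(roi_count); force(effects); force(baseline)
  function(row) {
    b <- effects$betas
    main <- b[c("intercept", "age", "sex", "group", "psqi")]
    z0 <- if (all(main == 0)) baseline else {
      b["intercept"] + b["age"] * row$age + b["sex"] * row$sex +
        b["group"] * row$group + b["psqi"] * row$psqi
    }
    z <- matrix(z0, roi_count, roi_count)
    aff <- effects$affected_edges
    dz <- b["group_x_psqi"] * row$group * row$psqi
    for (k in seq_len(nrow(aff))) {
      z[aff[k, 1], aff[k, 2]] <- z[aff[k, 1], aff[k, 2]] + dz
      z[aff[k, 2], aff[k, 1]] <- z[aff[k, 2], aff[k, 1]] + dz
    }
    r <- tanh(z)
    diag(r) <- 1
    dimnames(r) <- list(.default_roi_labels(roi_count),
                        .default_roi_labels(roi_count))
    r
  }
}

.default_roi_labels <- function(p) sprintf("ROI%03d", seq_len(p))

.all_pairs <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  edges <- cbind(i = idx[, "row"], j = idx[, "col"])
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# Canonical linear index of an unordered pair within a p-ROI atlas.
.edge_index <- function(edges, p) {
  (edges[, 1] - 1) * p + edges[, 2]
}

.edge_matrix_to_stack <- function(values, edges, p, labels, subject_ids) {
  n <- nrow(values)
  out <- array(NA_real_, dim = c(p, p, n),
               dimnames = list(labels, labels, subject_ids))
  for (s in seq_len(n)) {
    m <- matrix(NA_real_, p, p)
    m[edges] <- values[s, ]
    m[edges[, c(2, 1), drop = FALSE]] <- values[s, ]
    out[, , s] <- m
  }
  out
}

.validate_corr_target <- function(target, subject_id) {
  target <- as.matrix(target)
  if (nrow(target) != ncol(target) ||
      max(abs(target - t(target))) > 1e-8) {
    stop("target correlation for subject ", subject_id,
         " is not symmetric")
  }
  if (max(abs(diag(target) - 1)) > 1e-8) {
    stop("target correlation for subject ", subject_id,
         " must have unit diagonal")
  }
  target
}

# Nearest positive-definite correlation matrix: eigenvalue clipping at
# 1e-6 followed by renormalisation to unit diagonal.
.nearest_pd_corr <- function(R, eps = 1e-6) {
  es <- eigen(R, symmetric = TRUE)
  if (min(es$values) >= eps) return(R)
  vals <- pmax(es$values, eps)
  out <- es$vectors %*% (vals * t(es$vectors))
  out <- cov2cor(out)
  (out + t(out)) / 2
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset (", x$provenance$mode, " mode): ",
      nrow(x$cohort), " subjects\n", sep = "")
  if (!is.null(x$fc_observed)) {
    cat("  fc_observed:", paste(dim(x$fc_observed), collapse = " x "), "\n")
  }
  if (!is.null(x$timeseries)) {
    cat("  timeseries :", length(x$timeseries), "subjects x",
        nrow(x$timeseries[[1]]), "time points x",
        ncol(x$timeseries[[1]]), "ROIs\n")
  }
  invisible(x)
}
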