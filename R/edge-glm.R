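#' Build the second-level design matrix
#'
#' Fixed column order. Full model: intercept, age, sex, group, psqi,
#' group_x_psqi (the moderation term, the elementwise product of the
#' group and psqi columns). Simple model: intercept, age, sex, psqi (no
#' group term at all). Covariates enter in raw units; centering is
#' available because it changes the interpretation of lower-order terms
#' in an interaction model, and the choice is recorded in the returned
#' attribute.
#'
#' @param cohort a validated cohort table.
#' @param model \code{"full"} or \code{"simple"}.
#' @param center center age and psqi at their sample means (default
#'   \code{FALSE}, matching the raw-units formula).
#' @return numeric subjects x terms matrix with attributes
#'   \code{model_name} and \code{centered}; errors if any column is
#'   constant (rank deficiency).
#' @export
build_design <- function(cohort, model = c("full", "simple"),
                         center = FALSE) {
  validate_cohort(cohort)
  model <- match.arg(model)
  age <- cohort$age; psqi <- cohort$psqi
  if (center) {
    age <- age - mean(age); psqi <- psqi - mean(psqi)
  }
  X <- if (model == "full") {
    cbind(intercept = 1, age = age, sex = cohort$sex,
          group = cohort$group, psqi = psqi,
          group_x_psqi = cohort$group * psqi)
  } else {
    cbind(intercept = 1, age = age, sex = cohort$sex, psqi = psqi)
  }
  rownames(X) <- cohort$subject_id
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    variances <- apply(X[, -1, drop = FALSE], 2, stats::var)
    const <- names(variances)[variances == 0]
    if (length(const) > 0L) {
      stop("design is rank deficient: constant column(s) ",
           paste(const, collapse = ", "))
    }
    stop("design matrix is rank deficient")
  }
  attr(X, "model_name") <- model
  attr(X, "centered") <- center
  X
}

# Core OLS machinery shared by all fitting paths: Y is n x E (edges in
# columns). Returns coefficients, residuals, per-edge sigma^2 and the
# (X'X)^-1 diagonal needed for standard errors.
.ols_core <- function(Y, X) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("response and design row counts differ")
  if (anyNA(Y)) stop("response contains non-finite values")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is singular")
  coefs <- qr.coef(qx, Y)
  fitted <- X %*% coefs
  res <- Y - fitted
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("non-positive residual degrees of freedom")
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  list(coef = coefs, fitted = fitted, resid = res, df = df,
       sigma2 = colSums(res^2) / df, xtx_inv = xtx_inv)
}

# Vectorised t-statistics for one term over many edges. Used by the
# permutation loop, where speed matters: one precomputed projector, three
# matrix products per permutation.
.ols_projector <- function(X, term) {
  j <- match(term, colnames(X))
  if (is.na(j)) stop("term '", term, "' not in design")
  xtx_inv <- chol2inv(qr.R(qr(X)))
  list(X = X, pinv = xtx_inv %*% t(X), cjj = xtx_inv[j, j], j = j,
       df = nrow(X) - ncol(X))
}

.ols_tstats <- function(Y, proj) {
  B <- proj$pinv %*% Y
  res <- Y - proj$X %*% B
  sigma2 <- colSums(res^2) / proj$df
  B[proj$j, ] / sqrt(sigma2 * proj$cjj)
}

#' Fit one edge's GLM and test one term
#'
#' Ordinary least squares via QR decomposition; the t statistic for the
#' requested term, its two-tailed and one-tailed p-values from the t
#' distribution on the residual degrees of freedom. The two-tailed
#' p-value is \code{2 * min(p_left, p_right)}; the left tail is
#' \code{P(T <= t)}, the convention for reporting negative interactions.
#' Zero-residual-variance edges are flagged degenerate with \code{NaN}
#' statistics rather than erroring.
#'
#' @param y per-subject Fisher-z values for one edge.
#' @param X design matrix from [build_design()].
#' @param term tested column label (default the interaction).
#' @return list of class \code{"edge_fit"}: \code{beta} (all terms),
#'   \code{se}, \code{t}, \code{p_two}, \code{p_left}, \code{p_right},
#'   \code{df}, \code{degenerate}.
#' @examples
#' X <- cbind(intercept = 1, x = 0:3)
#' attr(X, "model_name") <- "custom"
#' fit_edge(c(1, 2, 2, 3), X, term = "x")  # slope 0.6, t = 4.243
#' @export
fit_edge <- function(y, X, term = "group_x_psqi") {
  if (any(!is.finite(y))) stop("non-finite values in edge response")
  core <- .ols_core(matrix(y, ncol = 1), X)
  j <- match(term, colnames(X))
  if (is.na(j)) stop("term '", term, "' not in design")
  se <- sqrt(core$sigma2[1] * diag(core$xtx_inv))
  tstat <- unname(core$coef[j, 1] / se[j])
  degenerate <- !is.finite(tstat)
  p_left <- pt(tstat, core$df)
  p_right <- pt(tstat, core$df, lower.tail = FALSE)
  structure(list(beta = core$coef[, 1], se = se, t = tstat,
                 p_two = 2 * min(p_left, p_right),
                 p_left = p_left, p_right = p_right,
                 df = core$df, term = term, degenerate = degenerate),
            class = "edge_fit")
}

#' @export
print.edge_fit <- function(x, ...) {
  cat(sprintf("edge fit: %s = %.6g (se %.6g), t = %.4f on %d df, p = %.4g\n",
              x$term, x$beta[x$term], x$se[x$term], x$t, x$df, x$p_two))
  invisible(x)
}

#' Fit the per-edge moderation GLM across a connectivity stack
#'
#' The central fitting function. Extracts each masked edge's Fisher-z
#' values across subjects, fits the second-level GLM
#' \code{z ~ 1 + age + sex + group * psqi} (or the simple model without
#' group) to every edge by ordinary least squares, and computes the
#' t statistic, tail p-values and Cohen's f2 effect size for the tested
#' term. Degenerate edges (zero residual variance) carry \code{NaN}
#' statistics and are flagged.
#'
#' @param fc ROI x ROI x subject array of Fisher-z connectivity (subjects
#'   aligned with \code{cohort} rows), or an n x E matrix of edge values
#'   when \code{mask} supplies the edge identities.
#' @param cohort cohort table aligned with the stack's subject dimension.
#' @param mask an [build_edge_mask()] result; \code{NULL} tests all
#'   unordered pairs.
#' @param model,term,center passed to [build_design()]; \code{term} is
#'   the tested column.
#' @return Object of class \code{"edge_glm"} with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{residuals},
#'   \code{fitted}, \code{plot} and \code{simulate}.
#' @examples
#' coh <- simulate_cohort(cohort_spec(seed = 3))
#' dat <- simulate_fc(coh, 8, effect_spec(noise_sd = 0.1), seed = 4)
#' fit <- edge_glm(dat$fc_observed, coh)
#' fit
#' head(summary(fit)$results, 3)
#' @export
edge_glm <- function(fc, cohort, mask = NULL,
                     model = c("full", "simple"),
                     term = "group_x_psqi", center = FALSE) {
  model <- match.arg(model)
  X <- build_design(cohort, model, center = center)
  if (!term %in% colnames(X)) {
    stop("term '", term, "' is not a column of the ", model, " model")
  }
  ext <- .extract_edges(fc, mask, n_subjects = nrow(cohort),
                        subject_ids = cohort$subject_id)
  Y <- ext$Y; edges <- ext$edges; labels <- ext$labels

  core <- .ols_core(Y, X)
  j <- match(term, colnames(X))
  se_all <- sqrt(outer(diag(core$xtx_inv), core$sigma2))
  tstat <- core$coef[j, ] / se_all[j, ]
  degenerate <- !is.finite(tstat) | .is_degenerate_var(core$sigma2, Y)
  tstat[degenerate] <- NaN
  p_left <- pt(tstat, core$df)
  p_right <- pt(tstat, core$df, lower.tail = FALSE)
  p_two <- 2 * pmin(p_left, p_right)

  f2 <- .cohens_f2_vec(Y, X, j)

  structure(list(call = match.call(), model = model, term = term,
                 design = X, edges = edges, roi_labels = labels,
                 beta = core$coef, se = se_all, t = tstat,
                 p_two = p_two, p_left = p_left, p_right = p_right,
                 df = core$df, sigma2 = core$sigma2,
                 residual_matrix = core$resid,
                 fitted_matrix = core$fitted,
                 f2 = f2$f2, f2_label = f2$label,
                 degenerate = degenerate, cohort = cohort,
                 mask_config = if (!is.null(mask)) attr(mask, "config")
                               else "all-pairs"),
            class = "edge_glm")
}

# Accept either a 3D stack + optional mask, or an n x E matrix + mask.
.extract_edges <- function(fc, mask, n_subjects, subject_ids) {
  if (length(dim(fc)) == 3L) {
    p <- dim(fc)[1]
    if (dim(fc)[3] != n_subjects) {
      stop("subject misalignment: stack has ", dim(fc)[3],
           " subjects, cohort has ", n_subjects,
           " (", paste(utils::head(subject_ids, 3), collapse = ", "),
           ", ...)")
    }
    labels <- dimnames(fc)[[1]]
    if (is.null(labels)) labels <- .default_roi_labels(p)
    edges <- if (is.null(mask)) .all_pairs(p) else
      cbind(i = mask$i, j = mask$j)
    if (any(edges > p)) stop("mask edge indices exceed stack dimension")
    idx <- edges[, 1] + (edges[, 2] - 1) * p
    Y <- t(apply(fc, 3, function(m) m[idx]))
    if (nrow(edges) == 1L) Y <- matrix(Y, ncol = 1)
    if (anyNA(Y)) stop("masked edges contain missing connectivity values")
    list(Y = Y, edges = edges, labels = labels)
  } else {
    fc <- as.matrix(fc)
    if (is.null(mask)) stop("a mask is required when fc is an edge matrix")
    if (nrow(fc) != n_subjects) stop("edge matrix rows must equal subjects")
    if (ncol(fc) != nrow(mask)) stop("edge matrix columns must match mask")
    list(Y = fc, edges = cbind(i = mask$i, j = mask$j),
         labels = attr(mask, "roi_names"))
  }
}

# Residual variance indistinguishable from floating-point noise relative
# to the response scale marks a degenerate (zero-variance) edge.
.is_degenerate_var <- function(sigma2, Y) {
  sigma2 < 1e-20 * (colMeans(Y^2) + 1e-300)
}

# f2 for one term across many edges: R^2 of the full fit vs the fit with
# that column dropped, over the residual proportion.
.cohens_f2_vec <- function(Y, X, j) {
  full <- .ols_core(Y, X)
  red <- .ols_core(Y, X[, -j, drop = FALSE])
  tss <- colSums(sweep(Y, 2, colMeans(Y), "-")^2)
  rss_f <- colSums(full$resid^2)
  rss_r <- colSums(red$resid^2)
  r2f <- 1 - rss_f / tss
  r2r <- 1 - rss_r / tss
  f2 <- (r2f - r2r) / (1 - r2f)
  f2[tss == 0] <- NaN
  list(f2 = f2, label = f2_label(f2))
}

#' Cohen's f2 for one model term
#'
#' Hierarchical effect size: \code{(R2_full - R2_reduced) /
#' (1 - R2_full)}, the proportion of variance uniquely explained by the
#' term relative to the residual variance, where the reduced model drops
#' only that term's column. Conventional bounds: below-small < 0.02 <=
#' small < 0.15 <= medium < 0.35 <= large.
#'
#' @param y response values for one edge.
#' @param X full design matrix.
#' @param term dropped column label.
#' @return list with \code{f2} and \code{label}.
#' @export
cohens_f2 <- function(y, X, term = "group_x_psqi") {
  j <- match(term, colnames(X))
  if (is.na(j)) stop("term '", term, "' not in design")
  out <- .cohens_f2_vec(matrix(y, ncol = 1), X, j)
  if (!is.finite(out$f2)) stop("undefined effect size: R2_full = 1")
  list(f2 = out$f2[1], label = out$label[1])
}

#' @rdname cohens_f2
#' @param f2 numeric vector of f2 values.
#' @export
f2_label <- function(f2) {
  ifelse(!is.finite(f2), NA_character_,
         ifelse(f2 >= 0.35, "large",
                ifelse(f2 >= 0.15, "medium",
                       ifelse(f2 >= 0.02, "small", "below-small"))))
}

#' Covariate-adjusted connectivity values
#'
#' Removes the demeaned age and sex contributions using the full-model
#' coefficients: \code{y - b_age (age - mean(age)) - b_sex (sex -
#' mean(sex))}. The adjusted values retain the group-wise PSQI
#' regression structure (intercept shifted to the covariate means), so
#' group-wise fitted lines on PSQI have the model-implied slopes
#' \code{b_psqi} and \code{b_psqi + b_int}; this is the quantity shown in
#' moderation scatter plots.
#'
#' @param y edge values (one per subject).
#' @param X full design matrix containing \code{age} and \code{sex}.
#' @param coefs optional named coefficient vector; defaults to the OLS
#'   fit of \code{y} on \code{X}.
#' @return adjusted values, same length as \code{y}.
#' @export
adjust_fc <- function(y, X, coefs = NULL) {
  if (!all(c("age", "sex") %in% colnames(X))) {
    stop("design must contain age and sex columns")
  }
  if (is.null(coefs)) {
    coefs <- .ols_core(matrix(y, ncol = 1), X)$coef[, 1]
  }
  age <- X[, "age"]; sex <- X[, "sex"]
  y - coefs["age"] * (age - mean(age)) - coefs["sex"] * (sex - mean(sex))
}

#' Symmetric t-statistic map over masked edges
#'
#' Convenience wrapper around [edge_glm()] returning the tested term's t
#' statistics as a symmetric ROI x ROI matrix; entries outside the mask
#' are \code{NA} (untested).
#'
#' @inheritParams edge_glm
#' @return list with \code{t} (symmetric matrix), \code{p_two},
#'   \code{p_left}, \code{p_right} (matrices), \code{df} and the
#'   underlying \code{"edge_glm"} fit.
#' @export
tmap <- function(fc, cohort, mask = NULL, model = "full",
                 term = "group_x_psqi") {
  fit <- edge_glm(fc, cohort, mask = mask, model = model, term = term)
  p <- length(fit$roi_labels)
  as_mat <- function(v) {
    m <- matrix(NA_real_, p, p,
                dimnames = list(fit$roi_labels, fit$roi_labels))
    m[fit$edges] <- v
    m[fit$edges[, c(2, 1), drop = FALSE]] <- v
    m
  }
  list(t = as_mat(fit$t), p_two = as_mat(fit$p_two),
       p_left = as_mat(fit$p_left), p_right = as_mat(fit$p_right),
       df = fit$df, fit = fit)
}

#' @export
print.edge_glm <- function(x, ...) {
  cat("Per-edge moderation GLM (", x$model, " model), term: ", x$term,
      "\n", sep = "")
  cat("  ", nrow(x$edges), " edges [", x$mask_config, "], ",
      nrow(x$design), " subjects, ", x$df, " residual df\n", sep = "")
  cat(sprintf("  t range: [%.3f, %.3f]; %d edges with p_two < 0.05 (raw)\n",
              min(x$t, na.rm = TRUE), max(x$t, na.rm = TRUE),
              sum(x$p_two < 0.05, na.rm = TRUE)))
  if (any(x$degenerate)) {
    cat("  ", sum(x$degenerate), "degenerate edge(s) flagged NaN\n")
  }
  invisible(x)
}

#' @export
summary.edge_glm <- function(object, fdr_q = 0.05, ...) {
  res <- edge_results(object, fdr_q = fdr_q)
  out <- list(results = res, model = object$model, term = object$term,
              df = object$df, fdr_q = fdr_q,
              n_rejected = sum(res$p_fdr <= fdr_q, na.rm = TRUE))
  class(out) <- "summary.edge_glm"
  out
}

#' @export
print.summary.edge_glm <- function(x, n = 10L, ...) {
  cat("Per-edge GLM summary: term", x$term, "| df", x$df, "|",
      x$n_rejected, "edges significant at FDR q =", x$fdr_q, "\n")
  print(utils::head(x$results, n), digits = 4)
  invisible(x)
}

#' Tidy per-edge results table
#'
#' One row per masked edge with coefficients, t, tail p-values,
#' BH-adjusted p-values and Cohen's f2; sorted by two-tailed p.
#'
#' @param fit an [edge_glm()] object.
#' @param fdr_q FDR level used for the adjusted-p rejection flag.
#' @return data.frame.
#' @export
edge_results <- function(fit, fdr_q = 0.05) {
  stopifnot(inherits(fit, "edge_glm"))
  fdr <- bh_fdr(ifelse(is.finite(fit$p_two), fit$p_two, 1), q = fdr_q)
  j <- match(fit$term, colnames(fit$design))
  out <- data.frame(
    roi_i = fit$roi_labels[fit$edges[, 1]],
    roi_j = fit$roi_labels[fit$edges[, 2]],
    beta_int = fit$beta[j, ], se = fit$se[j, ], t = fit$t, df = fit$df,
    p_two = fit$p_two, p_left = fit$p_left, p_fdr = fdr$p_adjusted,
    f2 = fit$f2, f2_label = fit$f2_label,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$p_two), ]
}

#' @export
coef.edge_glm <- function(object, ...) t(object$beta)

#' @export
residuals.edge_glm <- function(object, ...) object$residual_matrix

#' @export
fitted.edge_glm <- function(object, ...) object$fitted_matrix

#' @export
plot.edge_glm <- function(x, edge = 1L, ...) {
  y <- x$fitted_matrix[, edge] + x$residual_matrix[, edge]
  adj <- adjust_fc(y, x$design,
                   coefs = x$beta[, edge])
  psqi <- x$cohort$psqi; grp <- x$cohort$group
  plot(psqi, adj, col = ifelse(grp == 1, "firebrick", "steelblue"),
       pch = 19, xlab = "PSQI", ylab = "adjusted Fisher-z rsFC",
       main = paste(x$roi_labels[x$edges[edge, 1]], "-",
                    x$roi_labels[x$edges[edge, 2]]), ...)
  b <- x$beta[, edge]
  b0 <- b["intercept"] + b["age"] * mean(x$design[, "age"]) +
    b["sex"] * mean(x$design[, "sex"])
  if (x$model == "full") {
    graphics::abline(b0, b["psqi"], col = "steelblue", lwd = 2)
    graphics::abline(b0 + b["group"], b["psqi"] + b["group_x_psqi"],
                     col = "firebrick", lwd = 2)
    graphics::legend("topright", c("no-pain", "pain"), lwd = 2,
                     col = c("steelblue", "firebrick"), bty = "n")
  } else {
    graphics::abline(b0, b["psqi"], lwd = 2)
  }
  invisible(x)
}

#' @export
simulate.edge_glm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$design)
  E <- nrow(object$edges)
  mu <- object$fitted_matrix
  sigma <- sqrt(object$sigma2)
  replicate(nsim,
            mu + sweep(matrix(rnorm(n * E), n, E), 2, sigma, "*"),
            simplify = FALSE)
}
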