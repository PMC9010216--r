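#' Benjamini-Hochberg FDR over masked edges
#'
#' Step-up false-discovery-rate control: adjusted
#' \code{p_(k) = min_{j >= k} (m p_(j) / j)}, clipped at 1; an edge is
#' rejected iff its adjusted p-value is at most \code{q}, which matches
#' the classical step-up rule exactly. Adjustment is delegated to
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p raw p-values in \[0, 1\] over the masked edges.
#' @param q FDR level (default 0.05).
#' @return list of class \code{"fdr_result"}: \code{p_adjusted},
#'   \code{rejected} (logical), \code{q}, \code{n_rejected}.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))$rejected  # all TRUE
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (!.is_number(q) || q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  adj <- p.adjust(p, method = "BH")
  structure(list(p_adjusted = adj, rejected = adj <= q, q = q,
                 n_rejected = sum(adj <= q)),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("BH-FDR at q =", x$q, ":", x$n_rejected, "of", length(x$p_adjusted),
      "tests rejected\n")
  invisible(x)
}

#' TFNBS parameters
#'
#' Tuning constants of the threshold-free network-based statistic. The
#' per-threshold enhancement is \code{M(T) = e(T)^E * T^H} where
#' \code{e(T)} is the extent (edge count) of the supra-threshold
#' component containing the edge; scores integrate \code{M(T)} over
#' thresholds spaced \code{dT} apart. Defaults \code{E = 0.5},
#' \code{H = 2}, \code{dT = 0.1} and 1000 permutations.
#'
#' @param dT threshold step, in t-statistic units (> 0).
#' @param E extent exponent.
#' @param H height exponent.
#' @param tail \code{"two"} (statistic |t|), \code{"left"} (-t) or
#'   \code{"right"} (t).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param scheme \code{"freedman_lane"} (permute reduced-model residuals,
#'   preserving the nuisance structure; the default) or \code{"simple"}
#'   (joint whole-row permutation of the group and psqi columns).
#' @return list of class \code{"tfnbs_params"}.
#' @export
tfnbs_params <- function(dT = 0.1, E = 0.5, H = 2, tail = c("two", "left",
                                                            "right"),
                         n_perm = 1000, seed = 1L,
                         scheme = c("freedman_lane", "simple")) {
  if (!.is_number(dT) || dT <= 0) stop("dT must be > 0")
  if (!.is_number(E) || !.is_number(H)) stop("exponents must be finite")
  if (!.is_count(n_perm, 1L)) stop("n_perm must be a count >= 1")
  structure(list(dT = dT, E = E, H = H, tail = match.arg(tail),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 scheme = match.arg(scheme)),
            class = "tfnbs_params")
}

# Tail-adjusted statistic: the thresholded quantity is always "large
# means interesting under the chosen tail".
.tail_stat <- function(t, tail) {
  switch(tail, two = abs(t), left = -t, right = t)
}

#' Supra-threshold components at one threshold
#'
#' Thresholds the tail-adjusted statistic at \code{T} and groups the
#' surviving masked edges into components: maximal sets of edges
#' connected through shared ROI nodes. The extent of a component is its
#' edge count (the network-based-statistics convention).
#'
#' @param t_matrix symmetric t-statistic matrix (untested entries may be
#'   \code{NA}).
#' @param mask an [build_edge_mask()] result, or \code{NULL} for all
#'   pairs with finite statistics.
#' @param T threshold (> 0), applied to the tail-adjusted statistic.
#' @param tail \code{"two"}, \code{"left"} or \code{"right"}.
#' @return list of component records, each with \code{threshold},
#'   \code{member_edges} (matrix of roi index pairs) and \code{extent};
#'   empty list when nothing survives.
#' @export
components_at_threshold <- function(t_matrix, mask = NULL, T,
                                    tail = "two") {
  if (!.is_number(T) || T <= 0) stop("T must be > 0")
  edges <- .mask_edges(t_matrix, mask)
  s <- .tail_stat(t_matrix[edges], tail)
  keep <- which(is.finite(s) & s >= T - 1e-9)
  if (length(keep) == 0L) return(list())
  ke <- edges[keep, , drop = FALSE]
  comp <- edge_components_cpp(ke[, 1], ke[, 2], nrow(t_matrix))
  lapply(seq_len(max(comp)), function(cid) {
    members <- ke[comp == cid, , drop = FALSE]
    list(threshold = T, member_edges = members, extent = nrow(members))
  })
}

#' Threshold-free network-based statistic scores
#'
#' Integrates the component enhancement \code{e(T)^E * T^H} over the
#' threshold grid \code{T_k = k dT}, \code{k = 1..ceil(max_s / dT)},
#' where \code{max_s} is the largest tail-adjusted statistic: each
#' masked edge accumulates \code{extent^E * T^H * dT} at every threshold
#' it survives, with extent the edge count of its component at that
#' threshold. Edges never supra-threshold score 0; if no statistic is
#' positive under the chosen tail the score matrix is all zero.
#'
#' @inheritParams components_at_threshold
#' @param params a [tfnbs_params()] object (only \code{dT}, \code{E},
#'   \code{H}, \code{tail} are used here).
#' @return symmetric matrix of nonnegative scores; untested entries
#'   \code{NA}.
#' @export
tfnbs_scores <- function(t_matrix, mask = NULL, params = tfnbs_params()) {
  edges <- .mask_edges(t_matrix, mask)
  s <- .tail_stat(t_matrix[edges], params$tail)
  sc <- .tfnbs_edge_scores(edges, s, nrow(t_matrix), params)
  out <- matrix(NA_real_, nrow(t_matrix), ncol(t_matrix),
                dimnames = dimnames(t_matrix))
  out[edges] <- sc
  out[edges[, c(2, 1), drop = FALSE]] <- sc
  out
}

.tfnbs_edge_scores <- function(edges, s, n_nodes, params) {
  s[!is.finite(s)] <- 0
  s[s < 0] <- 0
  tfnbs_scores_cpp(edges[, 1], edges[, 2], s, n_nodes,
                   params$dT, params$E, params$H)
}

.mask_edges <- function(t_matrix, mask) {
  if (!is.null(mask)) {
    return(cbind(i = mask$i, j = mask$j))
  }
  edges <- .all_pairs(nrow(t_matrix))
  edges[is.finite(t_matrix[edges]), , drop = FALSE]
}

#' Permutation familywise-error test of TFNBS scores
#'
#' The main inference routine. Computes observed TFNBS scores from the
#' per-edge GLM t-map of the tested term, then builds the null
#' distribution of the \emph{maximum} score over masked edges by
#' permutation, and assigns each edge the familywise-error-corrected
#' p-value
#' \deqn{p_{FWE} = (1 + \#\{null\ maxima \ge score\}) / (1 + n_{perm}),}
#' the add-one convention guaranteeing validity and a minimum attainable
#' p of \code{1/(1 + n_perm)}.
#'
#' Two permutation schemes are available. \code{"freedman_lane"}
#' (default) fits the reduced model without the tested term, permutes
#' its residuals, adds back the reduced fit and refits the full model -
#' the standard way to test a single term while preserving nuisance
#' covariate structure. \code{"simple"} jointly permutes the group and
#' psqi rows of the design (rebuilding the interaction column), leaving
#' age and sex aligned with the subjects. Results record the scheme.
#'
#' @param fc connectivity stack (ROI x ROI x subject) or n x E edge
#'   matrix (then \code{mask} is required).
#' @param cohort cohort aligned with the stack.
#' @param mask an [build_edge_mask()] result or \code{NULL} (all pairs).
#' @param model,term model and tested column, as in [edge_glm()].
#' @param params a [tfnbs_params()].
#' @return object of class \code{"tfnbs_result"}: per-edge \code{score}s
#'   and \code{p_fwe}, the symmetric \code{score_matrix} and
#'   \code{p_fwe_matrix}, the \code{null_max} vector (one maximum per
#'   permutation), the observed t-map and the underlying fit.
#' @examples
#' coh <- simulate_cohort(cohort_spec(seed = 5))
#' dat <- simulate_fc(coh, 10, effect_spec(), seed = 6)
#' res <- tfnbs_test(dat$fc_observed, coh,
#'                   params = tfnbs_params(n_perm = 99, tail = "left",
#'                                         seed = 11))
#' res
#' @export
tfnbs_test <- function(fc, cohort, mask = NULL, model = "full",
                       term = "group_x_psqi",
                       params = tfnbs_params()) {
  stopifnot(inherits(params, "tfnbs_params"))
  fit <- edge_glm(fc, cohort, mask = mask, model = model, term = term)
  X <- fit$design
  Y <- fit$fitted_matrix + fit$residual_matrix
  edges <- fit$edges
  n_nodes <- length(fit$roi_labels)
  j <- match(term, colnames(X))

  s_obs <- .tail_stat(fit$t, params$tail)
  scores <- .tfnbs_edge_scores(edges, s_obs, n_nodes, params)

  proj_full <- .ols_projector(X, term)
  if (params$scheme == "freedman_lane") {
    Xr <- X[, -j, drop = FALSE]
    if (ncol(Xr) == 0L) {
      stop("freedman_lane scheme needs a nonempty reduced model")
    }
    red <- .ols_core(Y, Xr)
    Fr <- red$fitted
    Rr <- red$resid
  }

  n <- nrow(X)
  set.seed(params$seed)
  null_max <- numeric(params$n_perm)
  for (b in seq_len(params$n_perm)) {
    perm <- sample.int(n)
    if (params$scheme == "freedman_lane") {
      tp <- .ols_tstats(Fr + Rr[perm, , drop = FALSE], proj_full)
    } else {
      Xp <- X
      pcols <- intersect(c("group", "psqi"), colnames(X))
      Xp[, pcols] <- X[perm, pcols]
      if ("group_x_psqi" %in% colnames(X)) {
        Xp[, "group_x_psqi"] <- Xp[, "group"] * Xp[, "psqi"]
      }
      tp <- .ols_tstats(Y, .ols_projector(Xp, term))
    }
    sp <- .tail_stat(tp, params$tail)
    scp <- .tfnbs_edge_scores(edges, sp, n_nodes, params)
    null_max[b] <- if (length(scp) > 0L) max(scp) else 0
  }

  p_fwe <- (1 + vapply(scores, function(sc) sum(null_max >= sc),
                       numeric(1))) / (1 + params$n_perm)

  as_mat <- function(v) {
    m <- matrix(NA_real_, n_nodes, n_nodes,
                dimnames = list(fit$roi_labels, fit$roi_labels))
    m[edges] <- v
    m[edges[, c(2, 1), drop = FALSE]] <- v
    m
  }
  structure(list(score = scores, p_fwe = p_fwe,
                 score_matrix = as_mat(scores),
                 p_fwe_matrix = as_mat(p_fwe),
                 null_max = null_max, t = fit$t, edges = edges,
                 roi_labels = fit$roi_labels, params = params,
                 term = term, scheme = params$scheme, fit = fit),
            class = "tfnbs_result")
}

#' @export
print.tfnbs_result <- function(x, alpha = 0.05, ...) {
  cat("TFNBS permutation test | term:", x$term, "| tail:", x$params$tail,
      "| scheme:", x$scheme, "\n")
  cat(sprintf("  %d edges, %d permutations; max score %.3f (null max median %.3f)\n",
              length(x$score), x$params$n_perm, max(x$score),
              stats::median(x$null_max)))
  sig <- sum(x$p_fwe <= alpha)
  cat("  ", sig, " edge(s) with p_fwe <= ", alpha,
      " (min attainable p = ", format(1 / (1 + x$params$n_perm), digits = 3),
      ")\n", sep = "")
  invisible(x)
}

#' @export
summary.tfnbs_result <- function(object, alpha = 0.05, ...) {
  ord <- order(object$p_fwe, -object$score)
  data.frame(
    roi_i = object$roi_labels[object$edges[ord, 1]],
    roi_j = object$roi_labels[object$edges[ord, 2]],
    t = object$t[ord], tfnbs_score = object$score[ord],
    p_fwe = object$p_fwe[ord],
    significant = object$p_fwe[ord] <= alpha,
    stringsAsFactors = FALSE
  )
}

#' @export
plot.tfnbs_result <- function(x, ...) {
  graphics::hist(x$null_max, breaks = 30,
                 main = "Permutation null of maximum TFNBS score",
                 xlab = "max score", col = "grey85", border = "white",
                 ...)
  graphics::abline(v = max(x$score), col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("observed max = %.2f", max(x$score)), col =
                    "firebrick", side = 3, adj = 1, line = -1.2)
  invisible(x)
}

#' Export TFNBS results and the permutation null as TSV
#'
#' \code{write_tfnbs_results} writes one row per edge (t, tfnbs score,
#' p_fwe, tail, scheme, n_perm, seed); \code{write_null_max} writes the
#' permutation maxima for audit and re-thresholding.
#'
#' @param res a [tfnbs_test()] result.
#' @param path output file.
#' @export
write_tfnbs_results <- function(res, path) {
  df <- summary(res)
  df$tail <- res$params$tail
  df$scheme <- res$scheme
  df$n_perm <- res$params$n_perm
  df$seed <- res$params$seed
  .write_tsv(df, path)
}

#' @rdname write_tfnbs_results
#' @export
write_null_max <- function(res, path) {
  .write_tsv(data.frame(perm = seq_along(res$null_max),
                        max_score = res$null_max), path)
}
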