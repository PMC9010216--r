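#' Group summary statistics
#'
#' Container for (n, mean, sd) triples so that two-sample tests can be
#' run directly from printed summary tables as well as from raw data.
#'
#' @param n sample size (>= 2).
#' @param mean,sd sample mean and standard deviation (sd >= 0).
#' @return list of class \code{"group_summary"}.
#' @export
group_summary <- function(n, mean, sd) {
  if (!.is_count(n, 2L)) stop("n must be an integer >= 2")
  if (!.is_number(mean) || !.is_number(sd) || sd < 0) {
    stop("mean must be finite and sd >= 0")
  }
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

.as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x) && length(x) >= 2L) {
    return(group_summary(length(x), mean(x), sd(x)))
  }
  stop("expected a group_summary or a numeric vector of length >= 2")
}

.t_from_summaries <- function(a, b, t, df) {
  if (a$sd == 0 && b$sd == 0) {
    if (a$mean == b$mean) {
      return(list(t = 0, df = df, p_two = 1, degenerate = TRUE))
    }
    return(list(t = sign(a$mean - b$mean) * Inf, df = df, p_two = 0,
                degenerate = TRUE))
  }
  list(t = t, df = df, p_two = 2 * pt(-abs(t), df), degenerate = FALSE)
}

#' Welch two-sample t-test from summaries or raw data
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' the default for continuous group comparisons. Accepts either
#' [group_summary()] objects (so printed tables are directly checkable)
#' or raw numeric vectors.
#'
#' @param a,b [group_summary()] objects or numeric vectors.
#' @return list with \code{t}, \code{df}, \code{p_two} and a
#'   \code{degenerate} flag (both sds zero).
#' @examples
#' welch_t(group_summary(34, 6.88, 3.46), group_summary(14, 3.93, 3.00))
#' @export
welch_t <- function(a, b) {
  a <- .as_group_summary(a); b <- .as_group_summary(b)
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  .t_from_summaries(a, b, t, df)
}

#' Pooled-variance (Student) two-sample t-test
#'
#' Classical equal-variance t-test with \code{n1 + n2 - 2} degrees of
#' freedom. Provided alongside [welch_t()] because published tables mix
#' the two variants; reports should name which was used.
#'
#' @inheritParams welch_t
#' @return list with \code{t}, \code{df}, \code{p_two},
#'   \code{degenerate}.
#' @export
student_t <- function(a, b) {
  a <- .as_group_summary(a); b <- .as_group_summary(b)
  df <- a$n + b$n - 2
  if (df <= 0) stop("need n1 + n2 - 2 > 0")
  s2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  t <- (a$mean - b$mean) / sqrt(s2 * (1 / a$n + 1 / b$n))
  .t_from_summaries(a, b, t, df)
}

#' Pearson chi-square test on a contingency table
#'
#' \code{sum((O - E)^2 / E)} with expected counts from the row/column
#' marginals; optional Yates continuity correction for 2 x 2 tables.
#' Defaults to no correction. Zero marginals make expected counts
#' undefined and raise a validation error.
#'
#' @param counts nonnegative integer matrix of observed counts.
#' @param continuity apply the Yates correction (default \code{FALSE}).
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @examples
#' chi_square(matrix(c(8, 26, 7, 7), 2, byrow = TRUE))
#' @export
chi_square <- function(counts, continuity = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative")
  if (sum(counts) == 0) stop("contingency table is empty")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal: expected counts undefined")
  }
  res <- suppressWarnings(chisq.test(counts, correct = continuity))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' PSQI poor-sleeper flag
#'
#' A global PSQI sum of 5 or greater labels a poor sleeper (boundary
#' inclusive). Vectorised; scores outside the instrument's 0-21 range
#' are invalid.
#'
#' @param psqi_total global PSQI score(s).
#' @return logical vector.
#' @examples
#' poor_sleeper_flag(c(4, 5, 21))
#' @export
poor_sleeper_flag <- function(psqi_total) {
  if (any(!is.finite(psqi_total)) ||
      any(psqi_total < 0 | psqi_total > 21)) {
    stop("psqi_total must lie in [0, 21]")
  }
  psqi_total >= 5
}

#' Group-comparison table for a cohort
#'
#' Demographics-table style comparison between the pain and no-pain
#' groups: continuous variables get group means +/- SD and a two-sample
#' t-test (Welch by default), categorical variables get counts and a
#' Pearson chi-square test. Rows with p below \code{flag_threshold}
#' (a Bonferroni-style bound) are starred.
#'
#' @param cohort a cohort table.
#' @param variables cohort column names to compare (default age, psqi,
#'   sex).
#' @param categorical names within \code{variables} treated as
#'   categorical.
#' @param continuous_test \code{"welch"} or \code{"student"}.
#' @param flag_threshold p-value flagging threshold (default 0.001).
#' @return data.frame with columns \code{variable}, \code{pain},
#'   \code{nopain}, \code{test}, \code{statistic}, \code{df}, \code{p},
#'   \code{flag}.
#' @export
group_table <- function(cohort, variables = c("age", "psqi", "sex"),
                        categorical = "sex",
                        continuous_test = c("welch", "student"),
                        flag_threshold = 0.001) {
  validate_cohort(cohort)
  continuous_test <- match.arg(continuous_test)
  missing_vars <- setdiff(variables, names(cohort))
  if (length(missing_vars) > 0L) {
    stop("variables not in cohort: ", paste(missing_vars, collapse = ", "))
  }
  g1 <- cohort[cohort$group == 1, ]
  g0 <- cohort[cohort$group == 0, ]
  if (nrow(g1) == 0L || nrow(g0) == 0L) stop("empty group")
  rows <- lapply(variables, function(v) {
    if (v %in% categorical) {
      tab <- table(factor(cohort$group, levels = c(1, 0)), cohort[[v]])
      res <- chi_square(as.matrix(tab))
      data.frame(variable = v,
                 pain = paste(tab[1, ], collapse = "/"),
                 nopain = paste(tab[2, ], collapse = "/"),
                 test = "chi-square", statistic = res$chi2, df = res$df,
                 p = res$p, stringsAsFactors = FALSE)
    } else {
      a <- .as_group_summary(g1[[v]]); b <- .as_group_summary(g0[[v]])
      res <- if (continuous_test == "welch") welch_t(a, b) else
        student_t(a, b)
      data.frame(variable = v,
                 pain = sprintf("%.2f +/- %.2f", a$mean, a$sd),
                 nopain = sprintf("%.2f +/- %.2f", b$mean, b$sd),
                 test = paste0(continuous_test, "-t"),
                 statistic = res$t, df = res$df, p = res$p_two,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$flag <- ifelse(out$p < flag_threshold, "*", "")
  out
}
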