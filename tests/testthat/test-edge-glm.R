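test_that("design matrices have the declared columns and rank checks", {
  coh <- simulate_cohort(cohort_spec(seed = 1))
  X <- build_design(coh, "full")
  expect_equal(dim(X), c(48, 6))
  expect_equal(colnames(X), c("intercept", "age", "sex", "group", "psqi",
                              "group_x_psqi"))
  expect_equal(X[, "group_x_psqi"], X[, "group"] * X[, "psqi"])
  Xs <- build_design(coh, "simple")
  expect_equal(colnames(Xs), c("intercept", "age", "sex", "psqi"))
  allpain <- coh; allpain$group <- 1
  class(allpain) <- class(coh)
  expect_error(build_design(allpain, "full"), "per group")
  # same-group constant via direct construction
  chom <- make_cohort(age = rep(70, 6), sex = c(0, 1, 0, 1, 0, 1),
                      group = c(1, 1, 1, 0, 0, 0), psqi = c(4, 6, 8, 2, 3, 5))
  expect_error(build_design(chom, "full"), "constant column.*age")
})

test_that("the univariate fixture matches hand normal equations", {
  X <- cbind(intercept = 1, x = c(0, 1, 2, 3))
  fit <- fit_edge(c(1, 2, 2, 3), X, term = "x")
  expect_equal(unname(fit$beta["x"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(fit$se["x"]), 0.1414214, tolerance = 1e-6)
  expect_equal(fit$t, 4.242641, tolerance = 1e-6)
  expect_equal(fit$df, 2)
  expect_equal(fit$p_two, 2 * pt(-4.242641, 2), tolerance = 1e-6)
})

test_that("noiseless responses are fitted exactly", {
  coh <- simulate_cohort(cohort_spec(seed = 2))
  X <- build_design(coh, "full")
  b <- c(0.2, 0.01, -0.1, 0.05, 0.02, -0.03)
  y <- as.numeric(X %*% b)
  fit <- fit_edge(y, X)
  expect_lt(max(abs(fit$beta - b)), 1e-10)
  expect_lt(sum((y - as.numeric(X %*% fit$beta))^2), 1e-16)
})

test_that("edge fits agree with lm() on random data", {
  set.seed(77)
  coh <- simulate_cohort(cohort_spec(seed = 3))
  X <- build_design(coh, "full")
  y <- rnorm(48, sd = 0.2)
  fit <- fit_edge(y, X)
  ref <- lm(y ~ age + sex + group * psqi, data = cbind(coh, y = y))
  sm <- summary(ref)$coefficients
  expect_equal(unname(fit$beta["group_x_psqi"]), sm["group:psqi", 1],
               tolerance = 1e-10)
  expect_equal(fit$t, sm["group:psqi", 3], tolerance = 1e-10)
  expect_equal(fit$p_two, sm["group:psqi", 4], tolerance = 1e-10)
  expect_equal(fit$p_two, 2 * min(fit$p_left, fit$p_right),
               tolerance = 1e-14)
})

test_that("residuals are orthogonal to the design and t^2 equals partial F", {
  coh <- simulate_cohort(cohort_spec(seed = 4))
  dat <- simulate_fc(coh, 6, effect_spec(noise_sd = 0.2), seed = 5)
  fit <- edge_glm(dat$fc_observed, coh)
  X <- fit$design
  ortho <- crossprod(scale(X[, -1]), fit$residual_matrix)
  expect_lt(max(abs(ortho)) / nrow(X), 1e-8)
  # partial F for dropping the interaction equals t^2
  Y <- fit$fitted_matrix + fit$residual_matrix
  Xr <- X[, colnames(X) != "group_x_psqi"]
  for (e in c(1, 7, 15)) {
    rss_f <- sum(fit$residual_matrix[, e]^2)
    rss_r <- sum(lm.fit(Xr, Y[, e])$residuals^2)
    F <- (rss_r - rss_f) / (rss_f / fit$df)
    expect_equal(fit$t[e]^2, F, tolerance = 1e-8)
  }
})

test_that("null interaction p-values are uniform and type-I error nominal", {
  coh <- simulate_cohort(cohort_spec(seed = 6))
  eff <- effect_spec(affected_edges = matrix(integer(0), 0, 2),
                     beta_interaction = 0, noise_sd = 0.15)
  dat <- simulate_fc(coh, 64, eff, seed = 7)   # 2016 null edges
  fit <- edge_glm(dat$fc_observed, coh)
  ks <- suppressWarnings(ks.test(fit$p_two, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  rate <- mean(fit$p_two < 0.05)
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("Cohen's f2 follows its hierarchical definition", {
  coh <- simulate_cohort(cohort_spec(seed = 8))
  X <- build_design(coh, "full")
  set.seed(9)
  y <- as.numeric(X %*% c(0.2, 0, 0, 0, 0.01, -0.05)) + rnorm(48, sd = 0.1)
  out <- cohens_f2(y, X)
  # independent oracle via lm R-squared values
  r2f <- summary(lm(y ~ X[, -1]))$r.squared
  r2r <- summary(lm(y ~ X[, -c(1, 6)]))$r.squared
  expect_equal(out$f2, (r2f - r2r) / (1 - r2f), tolerance = 1e-10)
  # scale invariance
  out2 <- cohens_f2(100 * y + 3, X)
  expect_equal(out2$f2, out$f2, tolerance = 1e-10)
  # orthogonal term: remove the interaction's unique contribution, R2
  # unchanged when the column is dropped
  m_int <- lm.fit(X[, -6], X[, 6])$residuals
  y0 <- y - sum(m_int * y) / sum(m_int^2) * m_int
  expect_equal(cohens_f2(y0, X)$f2, 0, tolerance = 1e-10)
  expect_error(cohens_f2(as.numeric(X %*% rnorm(6)), X), "R2_full = 1")
})

test_that("f2 labels use the conventional thresholds and grow with the effect", {
  expect_equal(f2_label(c(0.01, 0.05, 0.2, 0.4)),
               c("below-small", "small", "medium", "large"))
  expect_equal(f2_label(0.15), "medium")
  expect_equal(f2_label(0.35), "large")
  coh <- simulate_cohort(cohort_spec(seed = 10))
  X <- build_design(coh, "full")
  set.seed(11)
  noise <- rnorm(48, sd = 0.15)
  f2s <- vapply(c(0.01, 0.03, 0.06, 0.12), function(b) {
    y <- as.numeric(X %*% c(0.2, 0, 0, 0, 0, -b)) + noise
    cohens_f2(y, X)$f2
  }, numeric(1))
  expect_true(all(diff(f2s) > 0))
})

test_that("covariate adjustment removes demeaned age/sex contributions", {
  coh <- simulate_cohort(cohort_spec(seed = 12))
  X <- build_design(coh, "full")
  b <- c(0.3, 0.004, -0.06, 0.05, 0.012, -0.025)
  y <- as.numeric(X %*% b)
  adj <- adjust_fc(y, X)
  manual <- b[1] + b[2] * mean(coh$age) + b[3] * mean(coh$sex) +
    b[4] * coh$group + (b[5] + b[6] * coh$group) * coh$psqi
  expect_lt(max(abs(adj - manual)), 1e-10)
  # no adjustment when age/sex coefficients vanish
  y2 <- as.numeric(X %*% c(0.3, 0, 0, 0.05, 0.012, -0.025))
  expect_equal(unname(adjust_fc(y2, X)), y2, tolerance = 1e-10)
  # translation invariance in age (demeaning)
  X2 <- X; X2[, "age"] <- X[, "age"] + 100
  expect_equal(adjust_fc(y, X, coefs = b), adjust_fc(y, X2, coefs = b),
               tolerance = 1e-10)
})

test_that("t-maps respect the mask and flag degenerate edges", {
  coh <- simulate_cohort(cohort_spec(seed = 13))
  dat <- simulate_fc(coh, 6, effect_spec(noise_sd = 0.1), seed = 14)
  mask <- make_mask(rbind(c(1, 2)), 6)
  tm <- tmap(dat$fc_observed, coh, mask = mask)
  expect_equal(sum(is.finite(tm$t[upper.tri(tm$t)])), 1)
  expect_true(is.finite(tm$t[1, 2]))
  # planted negative interaction, low noise: all affected edges negative
  datp <- simulate_fc(coh, 20, effect_spec(noise_sd = 0.02), seed = 15)
  tmp <- tmap(datp$fc_observed, coh)
  pn <- planted_network()
  expect_true(all(tmp$t[pn$edges] < 0))
  # identical values for all subjects -> degenerate NaN, flagged
  const <- simulate_fc(coh, 4,
                       effect_spec(affected_edges = matrix(integer(0), 0, 2),
                                   beta_intercept = 0.3,
                                   beta_interaction = 0,
                                   noise_sd = 0), seed = 16)
  fitc <- edge_glm(const$fc_observed, coh)
  expect_true(all(fitc$degenerate))
  expect_true(all(is.nan(fitc$t)))
})

test_that("the fit object supports the standard S3 generics", {
  coh <- simulate_cohort(cohort_spec(seed = 17))
  dat <- simulate_fc(coh, 6, effect_spec(noise_sd = 0.1), seed = 18)
  fit <- edge_glm(dat$fc_observed, coh)
  expect_equal(dim(coef(fit)), c(15, 6))
  expect_equal(dim(residuals(fit)), c(48, 15))
  expect_equal(fitted(fit) + residuals(fit),
               fitted(fit) + residuals(fit))
  res <- edge_results(fit)
  expect_true(!is.unsorted(res$p_two))
  expect_named(summary(fit), c("results", "model", "term", "df", "fdr_q",
                               "n_rejected"))
  sims <- simulate(fit, nsim = 2, seed = 19)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), c(48, 15))
  # simulated data refit: betas near the originals
  refit <- edge_glm(sims[[1]], coh,
                    mask = make_mask(fit$edges, 6))
  expect_lt(max(abs(refit$beta - fit$beta)), 1)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, edge = 1))
})
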