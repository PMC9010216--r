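test_that("noiseless constant effect yields exactly constant edges", {
  coh <- simulate_cohort(cohort_spec(seed = 3))
  eff <- effect_spec(beta_intercept = 0.3, beta_interaction = 0,
                     noise_sd = 0)
  dat <- simulate_fc(coh, 6, eff, seed = 4)
  vals <- dat$fc_observed[upper.tri(dat$fc_observed[, , 1])]
  expect_true(all(dat$fc_observed[1, 2, ] == 0.3))
  expect_true(all(vals == 0.3))
})

test_that("planted interaction follows linear-model arithmetic exactly", {
  # two otherwise-identical pain subjects differing only in psqi (10 vs 0)
  coh <- make_cohort(age = c(70, 70, 70, 70), sex = c(0, 0, 0, 0),
                     group = c(1, 1, 0, 0), psqi = c(10, 0, 10, 0))
  eff <- effect_spec(affected_edges = rbind(c(1, 2)),
                     beta_intercept = 0.3, beta_psqi = 0.01,
                     beta_interaction = -0.02, noise_sd = 0)
  dat <- simulate_fc(coh, 4, eff, seed = 1)
  diff_pain <- dat$fc_observed[1, 2, 1] - dat$fc_observed[1, 2, 2]
  expect_equal(diff_pain, -0.2 + 10 * 0.01, tolerance = 1e-12)
  # unaffected edge: only the psqi main effect
  diff_other <- dat$fc_observed[1, 3, 1] - dat$fc_observed[1, 3, 2]
  expect_equal(diff_other, 10 * 0.01, tolerance = 1e-12)
})

test_that("fc matrices are symmetric with undefined diagonal and reproducible", {
  coh <- simulate_cohort(cohort_spec(seed = 5))
  dat <- simulate_fc(coh, 8, effect_spec(), seed = 6)
  m <- dat$fc_observed[, , 3]
  expect_true(all(is.na(diag(m))))
  expect_equal(m, t(m))
  dat2 <- simulate_fc(coh, 8, effect_spec(), seed = 6)
  expect_identical(dat$fc_observed, dat2$fc_observed)
})

test_that("noiseless generation round-trips through the GLM fit", {
  coh <- simulate_cohort(cohort_spec(seed = 7))
  eff <- effect_spec(beta_intercept = 0.2, beta_age = 0.003,
                     beta_sex = -0.05, beta_group = 0.04,
                     beta_psqi = 0.01, beta_interaction = -0.03,
                     noise_sd = 0)
  dat <- simulate_fc(coh, 8, eff, seed = 8)
  fit <- edge_glm(dat$fc_observed, coh)
  truth <- c(0.2, 0.003, -0.05, 0.04, 0.01, -0.03)
  aff <- edge_keys(fit$edges) %in% planted_keys()
  expect_lt(max(abs(fit$beta[, aff] - truth)), 1e-10)
  truth0 <- truth; truth0[6] <- 0
  expect_lt(max(abs(fit$beta[, !aff] - truth0)), 1e-10)
})

test_that("exchangeable noise correlation couples edges within subject", {
  coh <- simulate_cohort(cohort_spec(n_pain = 300, n_nopain = 300,
                                     seed = 10))
  eff0 <- effect_spec(beta_interaction = 0, noise_sd = 0.2, rho = 0)
  eff9 <- effect_spec(beta_interaction = 0, noise_sd = 0.2, rho = 0.9)
  d0 <- simulate_fc(coh, 6, eff0, seed = 11)
  d9 <- simulate_fc(coh, 6, eff9, seed = 11)
  r0 <- cor(d0$fc_observed[1, 2, ], d0$fc_observed[3, 4, ])
  r9 <- cor(d9$fc_observed[1, 2, ], d9$fc_observed[3, 4, ])
  expect_lt(abs(r0), 0.2)
  expect_gt(r9, 0.6)
})

test_that("time-series mode honours target correlations", {
  coh <- make_cohort(age = c(70, 72, 68), sex = c(0, 1, 0),
                     group = c(1, 1, 0), psqi = c(6, 8, 3))
  # identity target: null correlations at 300 time points
  ident <- function(row) diag(5)
  dat <- simulate_timeseries(coh, ident, n_timepoints = 300, seed = 21)
  expect_equal(dim(dat$timeseries[[1]]), c(300, 5))
  r <- cor(dat$timeseries[[1]])
  expect_lt(max(abs(r[upper.tri(r)])), 0.25)
  # planted 0.6 correlation recovered at long series length
  tgt <- diag(4); tgt[1, 2] <- tgt[2, 1] <- 0.6
  dat2 <- simulate_timeseries(make_cohort(c(70, 72), c(0, 1), c(1, 0),
                                          c(5, 4)),
                              function(row) tgt,
                              n_timepoints = 10000, seed = 22)
  expect_lt(abs(cor(dat2$timeseries[[1]])[1, 2] - 0.6), 0.03)
  # determinism
  dat3 <- simulate_timeseries(coh, ident, n_timepoints = 300, seed = 21)
  expect_identical(dat$timeseries, dat3$timeseries)
})

test_that("invalid targets are rejected and non-PD targets projected", {
  coh <- make_cohort(c(70, 72), c(0, 1), c(1, 0), c(5, 4))
  asym <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(simulate_timeseries(coh, function(row) asym, 50, 1),
               "symmetric")
  baddiag <- matrix(c(2, 0, 0, 2), 2, 2)
  expect_error(simulate_timeseries(coh, function(row) baddiag, 50, 1),
               "diagonal")
  # pairwise -0.9 among 3 ROIs is not positive definite; projection makes
  # it factorisable and keeps the negative correlation structure
  npd <- matrix(-0.9, 3, 3); diag(npd) <- 1
  dat <- simulate_timeseries(coh, function(row) npd,
                             n_timepoints = 5000, seed = 3)
  r <- cor(dat$timeseries[[1]])
  expect_true(all(r[upper.tri(r)] < -0.3))
})

test_that("time-series pipeline recovers the sign of a planted interaction", {
  # calibration fixture: interaction large relative to correlation
  # sampling noise at 300 time points
  eff <- effect_spec(affected_edges = rbind(c(1, 2)),
                     beta_interaction = -0.06, noise_sd = 0)
  builder <- fc_target_builder(5, eff, baseline = 0.1)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    coh <- simulate_cohort(cohort_spec(seed = 400 + r))
    dat <- simulate_timeseries(coh, builder, n_timepoints = 300,
                               seed = 500 + r)
    fc <- compute_fc_stack(dat$timeseries)
    fit <- edge_glm(fc, coh)
    idx <- which(edge_keys(fit$edges) == "1 2")
    hits <- hits + (fit$t[idx] < 0)
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})

test_that("synthetic roi set exposes the planted stand-in roles", {
  rois <- synthetic_roi_set(20)
  expect_equal(attr(rois, "n_sleep"), 6)
  expect_equal(attr(rois, "n_union"), 8)
  mask <- build_edge_mask("S-SP", rois)
  expect_equal(attr(mask, "n_tests"), choose(6, 2) + 6 * 2)
  # every planted edge is inside the S-SP analog mask
  expect_true(all(planted_keys() %in% edge_keys(cbind(mask$i, mask$j))))
})
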