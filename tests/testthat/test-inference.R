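test_that("BH-FDR matches the step-up rule on worked examples", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$rejected))
  r2 <- bh_fdr(rep(1, 5))
  expect_false(any(r2$rejected))
  expect_true(all(r2$p_adjusted == 1))
  r3 <- bh_fdr(0.04, q = 0.05)
  expect_true(r3$rejected)
  expect_equal(r3$p_adjusted, 0.04)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(0.5, q = 1.5), "q must")
})

test_that("BH-FDR equals brute-force enumeration on random vectors", {
  set.seed(101)
  for (rep in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    r <- bh_fdr(p, q = 0.05)
    o <- bh_oracle(p, q = 0.05)
    expect_identical(r$rejected, o$rejected)
    expect_equal(r$p_adjusted, o$adjusted, tolerance = 1e-12)
    expect_true(all(r$p_adjusted >= p - 1e-15))
  }
})

test_that("supra-threshold components follow the node-sharing definition", {
  tm <- matrix(0, 5, 5)
  tm[1, 2] <- tm[2, 1] <- 3
  tm[2, 3] <- tm[3, 2] <- 2.5
  tm[4, 5] <- tm[5, 4] <- 2.2
  diag(tm) <- NA
  comps <- components_at_threshold(tm, T = 2, tail = "two")
  expect_length(comps, 2)
  extents <- sort(vapply(comps, `[[`, numeric(1), "extent"))
  expect_equal(extents, c(1, 2))
  comps2 <- components_at_threshold(tm, T = 2.7, tail = "two")
  expect_length(comps2, 1)
  expect_equal(comps2[[1]]$extent, 1)
  expect_equal(unname(comps2[[1]]$member_edges[1, ]), c(1, 2))
  expect_length(components_at_threshold(tm, T = 10), 0)
  expect_error(components_at_threshold(tm, T = -1), "T must")
})

test_that("component labelling equals BFS reachability on random graphs", {
  set.seed(202)
  for (rep in 1:40) {
    tm <- random_tmatrix(20, density = runif(1, 0.05, 0.4))
    for (T in c(0.5, 1, 2, 4)) {
      comps <- components_at_threshold(tm, T = T, tail = "two")
      kept <- which(!is.na(tm) & abs(tm) >= T - 1e-9 &
                      upper.tri(tm), arr.ind = TRUE)
      # union of member edges = supra-threshold set
      got <- do.call(rbind, lapply(comps, `[[`, "member_edges"))
      if (is.null(got)) got <- matrix(0L, 0, 2)
      expect_equal(nrow(got), nrow(kept))
      if (nrow(kept) > 0) {
        expect_setequal(edge_keys(got), edge_keys(kept))
        # partition sizes match the BFS oracle
        lab <- components_bfs_oracle(kept)
        expect_setequal(as.integer(table(lab)),
                        vapply(comps, `[[`, numeric(1), "extent"))
        # and the component count matches igraph (every vertex of the
        # edge-list graph carries at least one edge)
        g <- igraph::graph_from_edgelist(matrix(as.character(kept),
                                                ncol = 2),
                                         directed = FALSE)
        expect_equal(length(comps), igraph::components(g)$no)
      }
    }
  }
})

test_that("TFNBS scores match hand summations and the closed-form limit", {
  # isolated edge, s = 3: 0.001 * sum(k^2, k=1..30) = 9.455
  tm <- matrix(NA_real_, 4, 4)
  tm[1, 2] <- tm[2, 1] <- 3
  tm[3, 4] <- tm[4, 3] <- 0
  sc <- tfnbs_scores(tm, params = tfnbs_params())
  expect_equal(sc[1, 2], 9.455, tolerance = 1e-12)
  expect_equal(sc[3, 4], 0)
  # two edges sharing a node, s = (2, 1): two-regime summation
  tm2 <- matrix(NA_real_, 3, 3)
  tm2[1, 2] <- tm2[2, 1] <- 2
  tm2[2, 3] <- tm2[3, 2] <- 1
  sc2 <- tfnbs_scores(tm2, params = tfnbs_params())
  expect_equal(sc2[2, 3], sqrt(2) * 0.001 * 385, tolerance = 1e-10)
  expect_equal(sc2[1, 2], sqrt(2) * 0.001 * 385 + 0.001 * 2485,
               tolerance = 1e-10)
  # below the first threshold: zero
  tm3 <- matrix(NA_real_, 3, 3)
  tm3[1, 2] <- tm3[2, 1] <- 0.05
  expect_equal(tfnbs_scores(tm3, params = tfnbs_params())[1, 2], 0)
  # all-negative statistics under the right tail: zero matrix, no error
  tm4 <- matrix(-2, 3, 3); diag(tm4) <- NA
  sc4 <- tfnbs_scores(tm4, params = tfnbs_params(tail = "right"))
  expect_true(all(sc4[upper.tri(sc4)] == 0))
})

test_that("TFNBS equals the direct-summation oracle on random graphs", {
  set.seed(303)
  for (rep in 1:25) {
    tm <- random_tmatrix(15, density = 0.3)
    prm <- tfnbs_params(tail = sample(c("two", "left", "right"), 1))
    sc <- tfnbs_scores(tm, params = prm)
    edges <- which(!is.na(tm) & upper.tri(tm), arr.ind = TRUE)
    s <- switch(prm$tail, two = abs(tm[edges]), left = -tm[edges],
                right = tm[edges])
    oracle <- tfnbs_oracle(edges, s, prm$dT, prm$E, prm$H)
    expect_equal(unname(sc[edges]), oracle, tolerance = 1e-10)
  }
})

test_that("raising one statistic never lowers any TFNBS score", {
  set.seed(404)
  for (rep in 1:10) {
    tm <- abs(random_tmatrix(10, density = 0.4))
    sc <- tfnbs_scores(tm, params = tfnbs_params(tail = "right"))
    ut <- which(upper.tri(tm) & !is.na(tm) & tm > 0, arr.ind = TRUE)
    pick <- ut[sample(nrow(ut), 1), , drop = FALSE]
    tm2 <- tm
    tm2[pick] <- tm2[pick[, c(2, 1)]] <- tm[pick] + runif(1, 0.1, 2)
    sc2 <- tfnbs_scores(tm2, params = tfnbs_params(tail = "right"))
    expect_true(all(sc2[upper.tri(sc2)] >= sc[upper.tri(sc)] - 1e-12))
  }
})

test_that("permutation FWE p-values honour the add-one convention", {
  coh <- simulate_cohort(cohort_spec(seed = 21))
  dat <- simulate_fc(coh, 8, effect_spec(), seed = 22)
  res1 <- tfnbs_test(dat$fc_observed, coh,
                     params = tfnbs_params(n_perm = 1, seed = 23))
  expect_true(all(res1$p_fwe %in% c(0.5, 1)))
  res <- tfnbs_test(dat$fc_observed, coh,
                    params = tfnbs_params(n_perm = 99, seed = 23,
                                          tail = "left"))
  expect_true(all(res$p_fwe >= 1 / 100))
  expect_true(all(res$p_fwe <= 1))
  # monotone: higher score never has larger p
  o <- order(res$score)
  expect_true(all(diff(res$p_fwe[o]) <= 1e-12))
  # deterministic replay
  res2 <- tfnbs_test(dat$fc_observed, coh,
                     params = tfnbs_params(n_perm = 99, seed = 23,
                                           tail = "left"))
  expect_identical(res$null_max, res2$null_max)
  expect_identical(res$p_fwe, res2$p_fwe)
})

test_that("both permutation schemes run and record themselves", {
  coh <- simulate_cohort(cohort_spec(seed = 24))
  dat <- simulate_fc(coh, 6, effect_spec(), seed = 25)
  fl <- tfnbs_test(dat$fc_observed, coh,
                   params = tfnbs_params(n_perm = 50, seed = 26))
  sm <- tfnbs_test(dat$fc_observed, coh,
                   params = tfnbs_params(n_perm = 50, seed = 26,
                                         scheme = "simple"))
  expect_equal(fl$scheme, "freedman_lane")
  expect_equal(sm$scheme, "simple")
  expect_false(identical(fl$null_max, sm$null_max))
  df <- summary(fl)
  expect_true(all(c("roi_i", "roi_j", "tfnbs_score", "p_fwe") %in%
                    names(df)))
})

test_that("TSV exports of results and nulls are complete", {
  coh <- simulate_cohort(cohort_spec(seed = 27))
  dat <- simulate_fc(coh, 6, effect_spec(), seed = 28)
  res <- tfnbs_test(dat$fc_observed, coh,
                    params = tfnbs_params(n_perm = 20, seed = 29))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_tfnbs_results(res, p1)
  tab <- read.delim(p1)
  expect_equal(nrow(tab), length(res$score))
  expect_true(all(c("t", "tfnbs_score", "p_fwe", "tail", "scheme",
                    "n_perm", "seed") %in% names(tab)))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_null_max(res, p2)
  expect_equal(nrow(read.delim(p2)), 20)
})
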