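# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and its C++ kernel): BH by direct step-up
# enumeration, components by breadth-first reachability, TFNBS by direct
# Riemann summation over the oracle components.

# Brute-force Benjamini-Hochberg: rejection set by the step-up rule,
# adjusted p by the defining double minimum.
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) / m * q)
  rejected <- logical(m)
  if (length(ok) > 0L) rejected[o[seq_len(max(ok))]] <- TRUE
  adj_sorted <- vapply(seq_len(m), function(k) {
    min(1, min(m * ps[k:m] / (k:m)))
  }, numeric(1))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(rejected = rejected, adjusted = adjusted)
}

# Breadth-first-search connected components of an edge list. Returns an
# integer component label per edge.
components_bfs_oracle <- function(edges) {
  m <- nrow(edges)
  if (m == 0L) return(integer(0))
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  comp <- rep(NA_integer_, max(nodes))
  cid <- 0L
  for (v in nodes) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue) > 0L) {
      u <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      nb <- c(edges[edges[, 1] == u, 2], edges[edges[, 2] == u, 1])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp[edges[, 1]]
}

# Direct-summation TFNBS oracle built on the BFS components.
tfnbs_oracle <- function(edges, s, dT = 0.1, E = 0.5, H = 2) {
  score <- numeric(length(s))
  s <- pmax(s, 0)
  if (max(s) <= 0) return(score)
  kmax <- ceiling(max(s) / dT - 1e-9)
  for (k in seq_len(kmax)) {
    Tk <- k * dT
    keep <- which(s >= Tk - 1e-9)
    if (length(keep) == 0L) break
    lab <- components_bfs_oracle(edges[keep, , drop = FALSE])
    for (cid in unique(lab)) {
      idx <- keep[lab == cid]
      score[idx] <- score[idx] + length(idx)^E * Tk^H * dT
    }
  }
  score
}

# Random symmetric t-matrix on n nodes with a density of nonzero entries.
random_tmatrix <- function(n_nodes, density = 0.3, scale = 3) {
  m <- matrix(0, n_nodes, n_nodes)
  ut <- which(upper.tri(m))
  on <- sample(ut, ceiling(density * length(ut)))
  m[on] <- rnorm(length(on), 0, scale)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- NA_real_
  m
}

# Minimal edge_mask construction for ad-hoc test masks.
make_mask <- function(edges, n_rois, config = "test") {
  df <- data.frame(i = pmin(edges[, 1], edges[, 2]),
                   j = pmax(edges[, 1], edges[, 2]))
  df <- unique(df[order(df$i, df$j), ])
  rownames(df) <- NULL
  structure(df, config = config, n_tests = nrow(df),
            roi_names = sprintf("ROI%03d", seq_len(n_rois)),
            class = c("edge_mask", "data.frame"))
}

# Handmade cohort with full control over the covariates.
make_cohort <- function(age, sex, group, psqi) {
  out <- data.frame(
    subject_id = sprintf("S%02d", seq_along(age)),
    age = age, sex = sex, group = group, psqi = psqi,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort", "data.frame")
  out
}

# Planted-network bookkeeping shared by power/recovery tests.
planted_keys <- function() {
  pn <- planted_network()
  paste(pn$edges[, 1], pn$edges[, 2])
}

edge_keys <- function(edges) paste(edges[, 1], edges[, 2])
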