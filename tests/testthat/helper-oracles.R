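# Independent oracles and small generators shared across test files.

# Brute-force predictive-value sweep over a 0.1 % grid (vectorized; the
# prediction factorizes into per-axis >= indicators, so consistent counts are
# products of logical matrices). Independent of the breakpoint search in
# optimal_region().
brute_force_sweep <- function(results, step = 0.1) {
  g <- seq(0, 100, by = step)
  e <- results$observed == "E"
  drd <- outer(results$rd_pct, g, ">=")
  dra <- outer(results$ra_pct, g, ">=")
  m1 <- crossprod(drd[e, , drop = FALSE], dra[e, , drop = FALSE])
  m2 <- crossprod(!drd[!e, , drop = FALSE], !dra[!e, , drop = FALSE])
  list(grid = g, pv = 100 * (m1 + m2) / nrow(results))
}

# Random interaction-result sets for property tests; rates rounded to the 0.1 %
# grid so grid and exact searches see identical breakpoints.
random_results <- function(n, seed) {
  with_seed(seed, data.frame(
    drug_id = paste0("drug", seq_len(n)),
    interval_min = sample(c(1, 30, 60, 90, 120, 240), n, replace = TRUE),
    rd_pct = round(stats::runif(n, 0, 100), 1),
    ra_pct = round(stats::runif(n, 0, 100), 1),
    observed = sample(c("E", "NE"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# Published rate constants of the six studied drugs and the Rd/Ra cells the
# study reports for them (kd in s^-1, lags in hours, ka in h^-1).
table2_rd_cells <- function() {
  data.frame(
    drug_id = c(rep("amlodipine", 4), rep("bufferin", 2), rep("losartan", 2),
                rep("metoprolol_er", 2), rep("nifedipine", 3), "triazolam"),
    kd = c(rep(25.54e-4, 4), rep(27.64e-4, 2), rep(10.5e-4, 2),
           rep(1.03e-4, 2), rep(17.59e-4, 3), 14.69e-4),
    tlagd_h = 0,
    t_min = c(1, 30, 90, 240, 1, 60, 30, 60, 1, 60, 1, 30, 120, 1),
    printed = c(14.2, 99.0, 100.0, 100.0, 15.3, 100.0, 84.8, 97.7,
                0.6, 30.9, 10.0, 95.8, 99.8, 8.4)
  )
}

table2_ra_cells <- function() {
  data.frame(
    drug_id = c(rep("amlodipine", 4), rep("bufferin", 2), rep("losartan", 2),
                rep("metoprolol_er", 2), rep("nifedipine", 3), "triazolam"),
    ka = c(rep(0.62, 4), rep(1.55, 2), rep(1.43, 2), rep(0.11, 2),
           rep(2.49, 3), 17.34),
    tlaga_h = c(rep(0, 6), 0.33, 0.33, 0, 0, 0.28, 0.28, 0.28, 0.44),
    t_min = c(1, 30, 90, 240, 1, 60, 30, 60, 1, 60, 1, 30, 120, 1),
    printed = c(1.0, 26.8, 60.8, 91.8, 2.6, 78.8, 21.7, 61.6,
                0.2, 10.7, 0.0, 41.6, 98.6, 0.0)
  )
}

# Standard dense-early oral PK sampling schedule used in recovery studies.
pk_sampling_h <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12, 24)
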