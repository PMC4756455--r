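# Brute-force reference implementations, kept independent of the package
# code paths they check.

# Bray-Curtis by direct evaluation of the definition
bc_oracle <- function(a, b) sum(abs(a - b)) / sum(a + b)

# Spearman by explicit mid-ranking then the textbook Pearson sum formula,
# with the t approximation for the p-value
spearman_oracle <- function(x, y) {
  mid_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- mid_rank(x); ry <- mid_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rho <- num / den
  p <- if (abs(rho) >= 1) 0 else
    2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2)
  list(rho = rho, p = p)
}

# Benjamini-Hochberg step-up by the definition: q_(i) = min_{j>=i} p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(p[ord][js] * m / js, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# small cohort config for fast structural tests (overridable defaults)
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_pairs = 4, n_timepoints = 2, n_dropped_samples = 1,
         n_species = 12, n_modules = 8, n_markers_per_species = 40),
    list(...))
  do.call(cohort_config, args)
}

# minimal metadata grid: n_pairs x 2 subjects x n_timepoints, no dropouts
toy_metadata <- function(n_pairs = 2, n_timepoints = 2) {
  grid <- expand.grid(twin = c("A", "B"),
                      pair = sprintf("P%02d", seq_len(n_pairs)),
                      tp = seq_len(n_timepoints), stringsAsFactors = FALSE)
  metadata_table(data.frame(
    sample_id = sprintf("%s%s_T%d", grid$pair, grid$twin, grid$tp),
    subject_id = paste0(grid$pair, grid$twin),
    pair_id = grid$pair,
    timepoint = grid$tp,
    bmi = 20 + seq_len(nrow(grid)),
    stringsAsFactors = FALSE))
}
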