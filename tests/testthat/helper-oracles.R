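# Independent brute-force oracles used to cross-check the package's
# statistics, plus small fixture builders. Oracles are written from the
# textbook definitions, never by calling the code paths they check.

# Type-7 quantile: linear interpolation between order statistics.
quantile_type7_ref <- function(x, probs) {
  x <- sort(x)
  n <- length(x)
  vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, 0)
}

# Middle-of-sorted-vector median (mean of central pair for even n).
median_ref <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Kendall tau-b by counting concordant/discordant pairs over all C(n,2).
tau_b_ref <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  ties <- function(v) { t <- table(v); sum(t * (t - 1) / 2) }
  (C - D) / sqrt((n0 - ties(x)) * (n0 - ties(y)))
}

# Benjamini-Hochberg step-up from its definition.
bh_ref <- function(p) {
  m <- length(p)
  i <- order(p)
  sorted <- p[i]
  run <- rev(cummin(rev(sorted * m / seq_len(m))))
  adj <- numeric(m)
  adj[i] <- pmin(1, run)
  adj
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# assignments of the ranks of |d| (zero differences dropped; no ties).
wilcox_exact_ref <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  p <- if (V > n * (n + 1) / 4) 2 * mean(W >= V) else 2 * mean(W <= V)
  list(V = V, p = min(1, p))
}

# Kruskal-Wallis H with tie correction from the rank-sum formula.
kw_ref <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  Rj <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  t <- table(values)
  H / (1 - sum(t^3 - t) / (N^3 - N))
}

# Threshold counting straight off a per-base depth array.
perbase_counts_ref <- function(depth, depths) {
  vapply(depths, function(d) sum(depth >= d), 0)
}

# Random but valid covdata fixture: monotone counts within region length.
random_covdata <- function(seed, n_regions = 12, n_samples = 4,
                           depths = c(5, 10, 50, 100, 250, 500)) {
  set.seed(seed)
  len <- sample(50:200, n_regions, replace = TRUE)
  start <- cumsum(c(1000, len[-n_regions] + 100))
  regions <- data.frame(
    chrom = "chr1", start = start, end = start + len,
    region_id = sprintf("GENE%02d_ex%d", seq_len(n_regions), 1),
    stringsAsFactors = FALSE)
  counts <- array(0, dim = c(n_regions, length(depths), n_samples))
  for (i in seq_len(n_regions)) {
    for (s in seq_len(n_samples)) {
      counts[i, , s] <- sort(sample(0:len[i], length(depths),
                                    replace = TRUE), decreasing = TRUE)
    }
  }
  covdata(regions, depths, counts, sprintf("S%02d", seq_len(n_samples)))
}

# Single-region covdata with prescribed percent coverage per sample at
# one depth grid (region length 1000 so percents map to integer counts).
pcov_fixture <- function(p_by_sample_depth, depths) {
  n_s <- nrow(p_by_sample_depth)
  counts <- array(0, dim = c(1, length(depths), n_s))
  for (s in seq_len(n_s)) counts[1, , s] <- p_by_sample_depth[s, ] * 10
  cd <- covdata(
    data.frame(chrom = "chr1", start = 0L, end = 1000L,
               region_id = "GENE_ex1", stringsAsFactors = FALSE),
    depths, counts, sprintf("S%02d", seq_len(n_s)))
  percent_coverage(cd)
}
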