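# Core coverage statistics: percent coverage, the MPC statistic,
# per-sample quartile diagnostics, the run- and sample-level 75% quality
# rules, and the coverage MAD uniformity metric for CNV regions.

#' Default depth grid for a run type
#'
#' DNA runs (SNV and CNV calling) are evaluated at 50-500X; RNA runs at
#' 5-50X. The full covdata grid carries all six thresholds.
#'
#' @param run_type One of `"DNA"`, `"DNA_SNV"`, `"DNA_CNV"`, `"RNA"`,
#'   `"full"`.
#' @return Integer vector of depth thresholds, strictly increasing.
#' @export
depth_grid <- function(run_type = c("DNA", "DNA_SNV", "DNA_CNV", "RNA",
                                    "full")) {
  run_type <- match.arg(run_type)
  switch(run_type,
         DNA = , DNA_SNV = , DNA_CNV = c(50L, 100L, 250L, 500L),
         RNA = c(5L, 10L, 50L),
         full = c(5L, 10L, 50L, 100L, 250L, 500L))
}

#' Convert coverage counts to percent coverage
#'
#' The percent coverage `p` of a region at depth `D` is the percentage of
#' its bases covered at >= `D`: `p = 100 * count / (end - start)`.
#'
#' @param table A [covdata()] object.
#' @return An object of class `pcov`: the same regions/depths/samples with
#'   a `p` array of percent values in `[0, 100]`.
#' @export
percent_coverage <- function(table) {
  stopifnot(inherits(table, "covdata"))
  len <- table$regions$end - table$regions$start
  if (any(len <= 0)) stop("zero-length region")
  p <- sweep(table$counts, 1, len, "/") * 100
  structure(list(regions = table$regions, depths = table$depths,
                 samples = table$samples, p = p),
            class = "pcov")
}

#' Median percent coverage across samples
#'
#' For each (region, depth), the median of percent coverage `p` across
#' samples; with an even number of samples the mean of the two central
#' order statistics. MPC is the run-level reliability statistic for each
#' region.
#'
#' @param matrix A `pcov` object from [percent_coverage()].
#' @return An object of class `mpc_profile`: a numeric matrix of MPC
#'   values (regions x depths) with the region table and sample count as
#'   attributes.
#' @export
mpc <- function(matrix) {
  stopifnot(inherits(matrix, "pcov"))
  if (length(matrix$samples) < 1) stop("at least one sample is required")
  m <- apply(matrix$p, c(1, 2), stats::median)
  dim(m) <- dim(matrix$p)[1:2]
  dimnames(m) <- dimnames(matrix$p)[1:2]
  structure(m, class = "mpc_profile", regions = matrix$regions,
            depths = matrix$depths, n_samples = length(matrix$samples))
}

pcov_vector <- function(matrix, sample, depth, region_filter = NULL) {
  si <- match(as.character(sample), matrix$samples)
  di <- match(as.integer(depth), matrix$depths)
  if (is.na(si)) stop("unknown sample: ", sample)
  if (is.na(di)) stop("depth ", depth, "X not present in the table")
  v <- matrix$p[, di, si]
  if (!is.null(region_filter)) v <- v[region_filter]
  v
}

#' Quartile diagnostics of a sample's exon percent-coverage distribution
#'
#' Quartiles of the per-exon percent coverage at one depth, computed with
#' linear interpolation between order statistics (type-7 convention). The
#' sample is flagged when its first quartile falls below `threshold`,
#' i.e. when fewer than 75% of its exons reach 75% coverage under the
#' default rule.
#'
#' @param matrix A `pcov` object.
#' @param sample Sample identifier.
#' @param depth Depth threshold (must be present in the table).
#' @param region_filter Optional logical/integer index restricting the
#'   region set (e.g. CNV-calling regions only).
#' @param threshold Q1 rule threshold in percent (default 75).
#' @return One-row data frame: `sample`, `depth`, `n_regions`, `minimum`,
#'   `q1`, `q2`, `q3`, `maximum`, `flagged`.
#' @export
sample_quartiles <- function(matrix, sample, depth, region_filter = NULL,
                             threshold = 75) {
  v <- pcov_vector(matrix, sample, depth, region_filter)
  if (length(v) == 0) stop("no regions left after filtering")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(sample = as.character(sample), depth = as.integer(depth),
             n_regions = length(v), minimum = min(v), q1 = q[1], q2 = q[2],
             q3 = q[3], maximum = max(v), flagged = q[1] < threshold,
             stringsAsFactors = FALSE)
}

#' Per-sample diagnostic table across a depth grid
#'
#' @inheritParams sample_quartiles
#' @param depths Depth thresholds to evaluate (default: all in the table).
#' @return Data frame with one row per (sample, depth), columns as in
#'   [sample_quartiles()].
#' @export
sample_diagnostics <- function(matrix, depths = matrix$depths,
                               region_filter = NULL, threshold = 75) {
  rows <- list()
  for (s in matrix$samples) {
    for (d in depths) {
      rows[[length(rows) + 1L]] <-
        sample_quartiles(matrix, s, d, region_filter, threshold)
    }
  }
  do.call(rbind, rows)
}

#' Flag coverage-depleted samples
#'
#' A sample is flagged at depth `D` when the first quartile of its exon
#' percent-coverage distribution falls below the rule threshold
#' (inclusive pass at the threshold itself). Flags are independent across
#' depths.
#'
#' @inheritParams sample_diagnostics
#' @param grid Depth thresholds to evaluate.
#' @return Data frame `sample`, `depth`, `q1`, `flagged`.
#' @export
flag_depleted_samples <- function(matrix, grid = matrix$depths,
                                  region_filter = NULL, threshold = 75) {
  d <- sample_diagnostics(matrix, grid, region_filter, threshold)
  d[, c("sample", "depth", "q1", "flagged")]
}

#' Run-level quality report from an MPC profile
#'
#' A run should maximise the number of depths at which MPC reaches the
#' rule threshold (75% by default). MPC is a per-region statistic; the
#' run-level summary at each depth aggregates it over regions by the
#' regionwise median (default), mean, or the percentage of regions at or
#' above the threshold.
#'
#' @param profile An `mpc_profile` from [mpc()].
#' @param grid Depth thresholds to evaluate (must be present in the
#'   profile).
#' @param threshold Rule threshold in percent; a depth passes when its
#'   summary MPC is `>= threshold` (inclusive).
#' @param summary Aggregation over regions: `"median"`, `"mean"` or
#'   `"fraction"`.
#' @return Data frame `depth`, `summary_mpc`, `pass`, with attributes
#'   `n_pass`, `threshold` and `summary`.
#' @export
run_quality <- function(profile, grid = attr(profile, "depths"),
                        threshold = 75,
                        summary = c("median", "mean", "fraction")) {
  stopifnot(inherits(profile, "mpc_profile"))
  summary <- match.arg(summary)
  depths <- attr(profile, "depths")
  grid <- as.integer(grid)
  if (!all(grid %in% depths)) {
    stop("grid depth(s) not present in the MPC profile: ",
         paste(setdiff(grid, depths), collapse = ", "))
  }
  fn <- switch(summary,
               median = function(v) stats::median(v),
               mean = function(v) mean(v),
               fraction = function(v) 100 * mean(v >= threshold))
  sm <- vapply(grid, function(d) fn(profile[, match(d, depths)]), 0)
  out <- data.frame(depth = grid, summary_mpc = sm,
                    pass = sm >= threshold)
  attr(out, "n_pass") <- sum(out$pass)
  attr(out, "threshold") <- threshold
  attr(out, "summary") <- summary
  out
}

#' Coverage MAD compliance for CNV-calling regions
#'
#' Per-region mean depths for one sample are normalised by their median;
#' the coverage MAD is the raw median absolute deviation of the
#' normalised values (no consistency constant), a unitless uniformity
#' metric. The sample is compliant when the MAD does not exceed the
#' threshold (default 0.21).
#'
#' @param region_means Numeric vector of per-region mean depths (one
#'   sample, >= 2 regions, all positive).
#' @param threshold Compliance threshold (inclusive).
#' @return An object of class `cov_mad`: list with `mad`, `compliant`,
#'   `threshold`, `n_regions`.
#' @export
coverage_mad <- function(region_means, threshold = 0.21) {
  region_means <- as.numeric(region_means)
  if (length(region_means) < 2) stop("need at least 2 region means")
  if (any(!is.finite(region_means)) || any(region_means <= 0)) {
    stop("region means must be positive and finite")
  }
  x <- region_means / stats::median(region_means)
  m <- stats::median(abs(x - stats::median(x)))
  structure(list(mad = m, compliant = m <= threshold,
                 threshold = threshold, n_regions = length(region_means)),
            class = "cov_mad")
}

#' @export
print.cov_mad <- function(x, ...) {
  cat(sprintf("coverage MAD = %.4f over %d regions: %s (threshold <= %g)\n",
              x$mad, x$n_regions,
              if (x$compliant) "compliant" else "NOT compliant",
              x$threshold))
  invisible(x)
}
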