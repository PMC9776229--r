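# Wet-lab / sequencing metrics statistics: descriptives shaped like the
# validation tables, compliance flagging against documented thresholds,
# Kruskal-Wallis across runs with pairwise Mann-Whitney or Brown-Mood
# follow-up under FDR control, the paired pre-capture vs enriched library
# test, and Kendall tau-b correlation between metrics and coverage.

#' Validate a long-format metrics table
#'
#' Expected columns: `sample`, `run`, `nucleic` (`"DNA"`/`"RNA"`),
#' `metric`, `value`. `(sample, metric)` pairs must be unique.
#'
#' @param df Data frame to validate.
#' @return The validated data frame (invisibly usable in a pipeline).
#' @export
metrics_table <- function(df) {
  need <- c("sample", "run", "nucleic", "metric", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("metrics table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df[, c("sample", "metric")])) {
    stop("duplicated (sample, metric) pair in metrics table")
  }
  if (!all(df$nucleic %in% c("DNA", "RNA"))) {
    stop("nucleic must be 'DNA' or 'RNA'")
  }
  df$value <- as.numeric(df$value)
  df
}

#' Read a metrics table from TSV/CSV
#'
#' @param path File path; tab- or comma-separated, with header.
#' @return A validated metrics data frame (see [metrics_table()]).
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  metrics_table(utils::read.delim(path, sep = sep, header = TRUE,
                                  comment.char = "#",
                                  stringsAsFactors = FALSE))
}

#' Compliance rule presets for sample inclusion and run QC
#'
#' Two named presets are shipped and never merged, because they encode
#' different documented rule sets:
#' * `"section21"` — the sample-inclusion thresholds (DV200 >= 20%,
#'   Delta Cq <= 5, 260/280 within 1.6-1.8 for DNA and 1.8-2.0 for RNA,
#'   260/230 >= 2.0) plus the run-level coverage rules (median insert
#'   size >= 70, coverage MAD <= 0.21).
#' * `"table1"` — the per-metric "compliant value" annotations of the
#'   validation tables (concentration, absorbance, library yield and
#'   fragment-size windows).
#'
#' All comparisons are inclusive.
#'
#' @param preset `"section21"` or `"table1"`.
#' @return Data frame `metric`, `comparator` (`"ge"`, `"le"`,
#'   `"within"`), `lo`, `hi`, `applies_to`.
#' @export
compliance_rules <- function(preset = c("section21", "table1")) {
  preset <- match.arg(preset)
  r <- function(metric, comparator, lo, hi = NA_real_, applies_to) {
    data.frame(metric = metric, comparator = comparator, lo = lo, hi = hi,
               applies_to = applies_to, stringsAsFactors = FALSE)
  }
  if (preset == "section21") {
    rules <- rbind(
      r("dv200", "ge", 20, NA, "RNA"),
      r("delta_cq", "le", 5, NA, "DNA"),
      r("a260_280", "within", 1.6, 1.8, "DNA"),
      r("a260_280", "within", 1.8, 2.0, "RNA"),
      r("a260_230", "ge", 2.0, NA, "both"),
      r("median_insert_size", "ge", 70, NA, "DNA"),
      r("coverage_mad", "le", 0.21, NA, "DNA"))
  } else {
    rules <- rbind(
      r("conc", "ge", 3.5, NA, "DNA"),
      r("conc", "ge", 10.5, NA, "RNA"),
      r("a260_280", "ge", 2, NA, "both"),
      r("a260_230", "ge", 2, NA, "both"),
      r("delta_cq", "le", 5, NA, "DNA"),
      r("frag_qc", "within", 150, 300, "DNA"),
      r("dv200", "ge", 20, NA, "RNA"),
      r("pre_capture", "ge", 20, NA, "both"),
      r("enriched", "ge", 3, NA, "both"))
  }
  rules
}

apply_rule <- function(values, comparator, lo, hi) {
  switch(comparator,
         ge = values >= lo,
         le = values <= lo,
         within = values >= lo & values <= hi,
         stop("unknown comparator: ", comparator))
}

#' Flag samples against compliance rules
#'
#' Each rule is evaluated on every sample carrying the referenced metric
#' (restricted to the rule's nucleic type); comparisons are inclusive.
#'
#' @param table Metrics data frame (see [metrics_table()]).
#' @param rules Data frame from [compliance_rules()] (or same shape).
#' @return List with `flags` (per sample x rule: `sample`, `nucleic`,
#'   `metric`, `value`, `pass`) and `summary` (per rule: `n_compliant`,
#'   `n_evaluated`, `percent`).
#' @export
compliance_flags <- function(table, rules) {
  table <- metrics_table(table)
  unknown <- setdiff(rules$metric, unique(table$metric))
  if (length(unknown) > 0) {
    stop("compliance rule references unknown metric(s): ",
         paste(unknown, collapse = ", "))
  }
  flags <- list(); summ <- list()
  for (i in seq_len(nrow(rules))) {
    sel <- table$metric == rules$metric[i]
    if (rules$applies_to[i] != "both") {
      sel <- sel & table$nucleic == rules$applies_to[i]
    }
    sub <- table[sel, , drop = FALSE]
    if (nrow(sub) == 0) next
    pass <- apply_rule(sub$value, rules$comparator[i], rules$lo[i],
                       rules$hi[i])
    flags[[length(flags) + 1L]] <- data.frame(
      sample = sub$sample, nucleic = sub$nucleic, metric = sub$metric,
      value = sub$value, pass = pass, stringsAsFactors = FALSE)
    summ[[length(summ) + 1L]] <- data.frame(
      metric = rules$metric[i], applies_to = rules$applies_to[i],
      comparator = rules$comparator[i], lo = rules$lo[i], hi = rules$hi[i],
      n_compliant = sum(pass), n_evaluated = length(pass),
      percent = 100 * sum(pass) / length(pass), stringsAsFactors = FALSE)
  }
  list(flags = do.call(rbind, flags), summary = do.call(rbind, summ))
}

#' Per-run descriptive statistics for one metric
#'
#' Mean, sample standard deviation (n-1 denominator; reported `NA` for a
#' single value), median, min and max per run and overall, with a
#' formatted `"mean +/- sd / median [min; max]"` string matching the
#' shape of validation QC tables.
#'
#' @param table Metrics data frame.
#' @param metric Metric name.
#' @param nucleic Optional `"DNA"`/`"RNA"` restriction.
#' @return Data frame with one row per run plus an `"overall"` row.
#' @export
describe_by_run <- function(table, metric, nucleic = NULL) {
  table <- metrics_table(table)
  sub <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(nucleic)) sub <- sub[sub$nucleic == nucleic, , drop = FALSE]
  if (nrow(sub) == 0) stop("no values for metric '", metric, "'")
  one <- function(v, label) {
    s <- if (length(v) > 1) stats::sd(v) else NA_real_
    data.frame(run = label, n = length(v), mean = mean(v), sd = s,
               median = stats::median(v), min = min(v), max = max(v),
               formatted = sprintf("%.4g ± %.4g / %.4g [%.4g; %.4g]",
                                   mean(v), s, stats::median(v), min(v),
                                   max(v)),
               stringsAsFactors = FALSE)
  }
  runs <- sort(unique(sub$run))
  out <- do.call(rbind, lapply(runs, function(r) {
    one(sub$value[sub$run == r], as.character(r))
  }))
  rbind(out, one(sub$value, "overall"))
}

#' Kruskal-Wallis test of a metric across groups
#'
#' Rank-based H statistic with tie correction, p-value from the
#' chi-square distribution with k-1 degrees of freedom (via
#' [stats::kruskal.test()]). When all values are identical the test is
#' degenerate and `H = 0`, `p = 1` is returned rather than an error.
#'
#' @param table Metrics data frame.
#' @param metric Metric name.
#' @param by Grouping column (default `"run"`).
#' @param nucleic Optional `"DNA"`/`"RNA"` restriction.
#' @return Data frame row: `metric`, `method`, `statistic`, `df`,
#'   `p_value`, `n_groups`.
#' @export
kruskal_wallis <- function(table, metric, by = "run", nucleic = NULL) {
  table <- metrics_table(table)
  sub <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(nucleic)) sub <- sub[sub$nucleic == nucleic, , drop = FALSE]
  g <- factor(sub[[by]])
  if (nlevels(g) < 2) stop("Kruskal-Wallis needs at least 2 groups")
  if (length(unique(sub$value)) == 1) {
    return(data.frame(metric = metric, method = "Kruskal-Wallis",
                      statistic = 0, df = nlevels(g) - 1, p_value = 1,
                      n_groups = nlevels(g), stringsAsFactors = FALSE))
  }
  kt <- stats::kruskal.test(sub$value, g)
  data.frame(metric = metric, method = "Kruskal-Wallis",
             statistic = unname(kt$statistic), df = unname(kt$parameter),
             p_value = kt$p.value, n_groups = nlevels(g),
             stringsAsFactors = FALSE)
}

brown_mood_test <- function(x, y) {
  m <- stats::median(c(x, y))
  tab <- rbind(c(sum(x > m), sum(x <= m)),
               c(sum(y > m), sum(y <= m)))
  ft <- stats::fisher.test(tab)
  list(statistic = tab[1, 1], p_value = ft$p.value)
}

#' Pairwise between-group tests with FDR adjustment
#'
#' All k(k-1)/2 group pairs are tested with the Mann-Whitney rank-sum
#' test (default) or the Brown-Mood median test (2x2 exact test on
#' counts above the pooled median). P-values are adjusted over the pair
#' family with the Benjamini-Hochberg step-up procedure (or
#' Benjamini-Yekutieli).
#'
#' @param table Metrics data frame.
#' @param metric Metric name.
#' @param by Grouping column (default `"run"`).
#' @param method `"mann_whitney"` or `"brown_mood"`.
#' @param adjust `"BH"`, `"BY"` or `"none"`.
#' @param nucleic Optional `"DNA"`/`"RNA"` restriction.
#' @return Data frame: `metric`, `group1`, `group2`, `method`,
#'   `statistic`, `p_value`, `adjusted_p`.
#' @export
pairwise_tests <- function(table, metric, by = "run",
                           method = c("mann_whitney", "brown_mood"),
                           adjust = c("BH", "BY", "none"), nucleic = NULL) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  table <- metrics_table(table)
  sub <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(nucleic)) sub <- sub[sub$nucleic == nucleic, , drop = FALSE]
  g <- factor(sub[[by]])
  lv <- levels(g)
  if (length(lv) < 2) stop("pairwise tests need at least 2 groups")
  pairs <- utils::combn(lv, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    x <- sub$value[g == pairs[1, j]]
    y <- sub$value[g == pairs[2, j]]
    if (length(x) == 0 || length(y) == 0) {
      warning("skipping pair ", pairs[1, j], " vs ", pairs[2, j],
              ": empty group")
      next
    }
    res <- if (method == "mann_whitney") {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      list(statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      brown_mood_test(x, y)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      metric = metric, group1 = pairs[1, j], group2 = pairs[2, j],
      method = method, statistic = res$statistic, p_value = res$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- if (adjust == "none") out$p_value else
    stats::p.adjust(out$p_value, method = adjust)
  out
}

#' Paired pre-capture vs enriched library test
#'
#' Wilcoxon signed-rank test of enriched against pre-capture library
#' values on samples measured at both checkpoints, stratified by nucleic
#' type. Zero differences are dropped before ranking (classic
#' convention; `zero_method = "signed"` keeps them with sign ranks via
#' the normal approximation). The exact distribution is used for n <= 25
#' without ties, the normal approximation with tie correction otherwise.
#' When every difference is zero the result is degenerate: `p = 1`,
#' direction `"none"`.
#'
#' @param table Metrics data frame containing both metrics.
#' @param pre,post Metric names of the paired measurements.
#' @param zero_method `"drop"` (default) or `"signed"`.
#' @return Data frame with one row per nucleic type: `nucleic`, `n_pairs`,
#'   `n_zero`, `statistic`, `p_value`, `direction`, `median_change`,
#'   `degenerate`.
#' @export
paired_library_test <- function(table, pre = "pre_capture",
                                post = "enriched",
                                zero_method = c("drop", "signed")) {
  zero_method <- match.arg(zero_method)
  table <- metrics_table(table)
  rows <- list()
  for (nt in intersect(c("DNA", "RNA"), unique(table$nucleic))) {
    a <- table[table$nucleic == nt & table$metric == pre, ]
    b <- table[table$nucleic == nt & table$metric == post, ]
    common <- intersect(a$sample, b$sample)
    if (length(common) == 0) next
    d <- b$value[match(common, b$sample)] - a$value[match(common, a$sample)]
    nz <- sum(d == 0)
    md <- stats::median(d)
    dd <- if (zero_method == "drop") d[d != 0] else d
    if (length(dd) == 0 || all(dd == 0)) {
      rows[[length(rows) + 1L]] <- data.frame(
        nucleic = nt, n_pairs = length(d), n_zero = nz,
        statistic = NA_real_, p_value = 1, direction = "none",
        median_change = md, degenerate = TRUE, stringsAsFactors = FALSE)
      next
    }
    exact <- zero_method == "drop" && length(dd) <= 25 &&
      !any(duplicated(abs(dd)))
    wt <- suppressWarnings(stats::wilcox.test(dd, exact = exact))
    rows[[length(rows) + 1L]] <- data.frame(
      nucleic = nt, n_pairs = length(d), n_zero = nz,
      statistic = unname(wt$statistic), p_value = wt$p.value,
      direction = if (md < 0) "decrease" else if (md > 0) "increase"
                  else "none",
      median_change = md, degenerate = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Kendall tau-b with p-value and asymptotic confidence interval
#'
#' Tie-corrected Kendall rank correlation via [stats::cor.test()]
#' (exact p for small untied samples, normal approximation otherwise).
#' The 95% confidence interval uses the asymptotic standard error
#' `sqrt(2 (2n + 5) / (9 n (n - 1)))`, clipped to `[-1, 1]`.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame row: `n`, `tau`, `p_value`, `ci_low`, `ci_high`.
#' @export
tau_test <- function(x, y, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Kendall correlation needs at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("Kendall correlation undefined for a constant variable")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  tau <- unname(ct$estimate)
  se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(n = n, tau = tau, p_value = ct$p.value,
             ci_low = max(-1, tau - z * se),
             ci_high = min(1, tau + z * se))
}

#' Coverage summaries per sample for correlation analysis
#'
#' Reshapes a per-sample diagnostic table into the per-sample coverage
#' variables used against wet metrics: the median exon percent coverage
#' (Q2) at each depth, labelled by variant type.
#'
#' @param diagnostics Data frame from [sample_diagnostics()].
#' @param variant_type Label, e.g. `"SNV"`, `"CNV"` or `"RNA"`.
#' @return Data frame `sample`, `stratum` (`"<type>_<depth>X"`), `value`.
#' @export
coverage_q2 <- function(diagnostics, variant_type) {
  data.frame(sample = diagnostics$sample,
             stratum = paste0(variant_type, "_", diagnostics$depth, "X"),
             value = diagnostics$q2, stringsAsFactors = FALSE)
}

#' Kendall tau correlation between wet metrics and coverage
#'
#' For every metric and every coverage stratum (variant type x depth,
#' optionally further split by run), samples present in both tables are
#' paired and [tau_test()] applied. Strata with fewer than 3 complete
#' pairs are skipped with a warning.
#'
#' @param metrics Metrics data frame (see [metrics_table()]).
#' @param coverage Data frame `sample`, `stratum`, `value` as returned by
#'   [coverage_q2()].
#' @param metrics_list Metric names to use (default: all in `metrics`).
#' @param by_run Also stratify by the metrics table's `run` column.
#' @return Data frame: `metric`, `stratum`, `run`, `n`, `tau`,
#'   `p_value`, `ci_low`, `ci_high`.
#' @export
tau_correlation <- function(metrics, coverage, metrics_list = NULL,
                            by_run = FALSE) {
  metrics <- metrics_table(metrics)
  if (is.null(metrics_list)) metrics_list <- unique(metrics$metric)
  runs <- if (by_run) sort(unique(metrics$run)) else NA
  rows <- list()
  for (m in metrics_list) {
    mm <- metrics[metrics$metric == m, , drop = FALSE]
    for (st in unique(coverage$stratum)) {
      cc <- coverage[coverage$stratum == st, , drop = FALSE]
      for (r in runs) {
        mr <- if (is.na(r)) mm else mm[mm$run == r, , drop = FALSE]
        common <- intersect(mr$sample, cc$sample)
        x <- mr$value[match(common, mr$sample)]
        y <- cc$value[match(common, cc$sample)]
        ok <- stats::complete.cases(x, y)
        if (sum(ok) < 3 || length(unique(x[ok])) == 1 ||
            length(unique(y[ok])) == 1) {
          warning("skipping stratum ", m, " x ", st,
                  if (!is.na(r)) paste0(" (run ", r, ")"),
                  ": <3 complete pairs or constant variable")
          next
        }
        tt <- tau_test(x, y)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(metric = m, stratum = st, run = r,
                     stringsAsFactors = FALSE), tt)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(metric = character(), stratum = character(),
                      run = integer(), n = integer(), tau = numeric(),
                      p_value = numeric(), ci_low = numeric(),
                      ci_high = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a tau correlation matrix as TSV and heatmap
#'
#' Writes `<prefix>.tsv` (metrics x coverage strata, cells = tau) and
#' `<prefix>.pdf`, a heatmap in which cells significant at p < 0.05 are
#' starred.
#'
#' @param results Data frame from [tau_correlation()] (single run level).
#' @param prefix Output path prefix.
#' @param alpha Significance mark threshold (default 0.05).
#' @return Invisibly, a list with the tau `matrix` and the two `paths`.
#' @export
heatmap_export <- function(results, prefix, alpha = 0.05) {
  if (nrow(results) == 0) stop("no tau results to export")
  mets <- unique(results$metric)
  strata <- unique(results$stratum)
  tau <- matrix(NA_real_, length(mets), length(strata),
                dimnames = list(mets, strata))
  pv <- tau
  for (i in seq_len(nrow(results))) {
    tau[results$metric[i], results$stratum[i]] <- results$tau[i]
    pv[results$metric[i], results$stratum[i]] <- results$p_value[i]
  }
  tsv <- paste0(prefix, ".tsv")
  out <- data.frame(metric = rownames(tau), tau, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fig <- paste0(prefix, ".pdf")
  grDevices::pdf(fig, width = 2 + ncol(tau), height = 2 + 0.5 * nrow(tau))
  on.exit(grDevices::dev.off())
  z <- t(tau)[, rev(seq_len(nrow(tau))), drop = FALSE]
  graphics::image(seq_len(ncol(tau)), seq_len(nrow(tau)), z,
                  zlim = c(-1, 1),
                  col = grDevices::hcl.colors(41, "Blue-Red 2"),
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, seq_len(ncol(tau)), colnames(tau), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(tau)), rev(rownames(tau)), las = 2,
                 cex.axis = 0.8)
  for (i in seq_len(nrow(tau))) {
    for (j in seq_len(ncol(tau))) {
      if (is.na(tau[i, j])) next
      lab <- sprintf("%.2f%s", tau[i, j],
                     if (!is.na(pv[i, j]) && pv[i, j] < alpha) "*" else "")
      graphics::text(j, nrow(tau) - i + 1, lab, cex = 0.7)
    }
  }
  graphics::box()
  invisible(list(matrix = tau, paths = c(tsv, fig)))
}
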