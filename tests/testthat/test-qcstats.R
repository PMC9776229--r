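mk_metrics <- function(values, metric = "m", nucleic = "DNA",
                       run = NULL, prefix = "S") {
  n <- length(values)
  if (is.null(run)) run <- rep(1L, n)
  data.frame(sample = sprintf("%s%03d", prefix, seq_len(n)), run = run,
             nucleic = nucleic, metric = metric, value = values,
             stringsAsFactors = FALSE)
}

test_that("compliance comparisons are inclusive and fractions count correctly", {
  rules <- compliance_rules("section21")
  tab <- rbind(mk_metrics(c(19.99, 20, 20.01), "dv200", "RNA"),
               mk_metrics(c(4.99, 5, 5.01), "delta_cq", "DNA",
                          prefix = "D"))
  fl <- compliance_flags(tab, rules[rules$metric %in% c("dv200",
                                                        "delta_cq"), ])
  dv <- fl$flags[fl$flags$metric == "dv200", ]
  expect_equal(dv$pass, c(FALSE, TRUE, TRUE))
  dc <- fl$flags[fl$flags$metric == "delta_cq", ]
  expect_equal(dc$pass, c(TRUE, TRUE, FALSE))
  expect_equal(fl$summary$n_compliant, c(2L, 2L))
  expect_equal(fl$summary$n_evaluated, c(3L, 3L))

  # all samples violating a rule -> fraction 0/n
  bad <- mk_metrics(rep(10, 4), "dv200", "RNA")
  fl0 <- compliance_flags(bad, rules[rules$metric == "dv200", ])
  expect_equal(fl0$summary$percent, 0)

  # randomized counting oracle
  set.seed(5)
  v <- stats::runif(50, 0, 10)
  flr <- compliance_flags(mk_metrics(v, "delta_cq", "DNA"),
                          rules[rules$metric == "delta_cq", ])
  expect_equal(flr$summary$n_compliant, sum(v <= 5))

  expect_error(compliance_flags(mk_metrics(1:3),
                                data.frame(metric = "nope",
                                           comparator = "ge", lo = 1,
                                           hi = NA, applies_to = "both")),
               "unknown metric")
})

test_that("per-run descriptives match two-pass reference formulas", {
  d <- describe_by_run(mk_metrics(c(1, 2, 3)), "m")
  expect_equal(d$mean, c(2, 2))
  expect_equal(d$sd, c(1, 1))
  expect_equal(d$median, c(2, 2))
  expect_equal(d$min, c(1, 1))
  expect_equal(d$max, c(3, 3))

  # single value: sd absent, median = mean = value
  d1 <- describe_by_run(mk_metrics(7), "m")
  expect_true(is.na(d1$sd[1]))
  expect_equal(d1$median[1], 7)

  set.seed(13)
  v <- stats::rnorm(40, 10, 3)
  run <- rep(1:5, 8)
  d5 <- describe_by_run(mk_metrics(v, run = run), "m")
  for (r in 1:5) {
    x <- v[run == r]
    expect_equal(d5$mean[d5$run == r], sum(x) / length(x),
                 tolerance = 1e-12)
    expect_equal(d5$sd[d5$run == r],
                 sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
                 tolerance = 1e-12)
    expect_equal(d5$median[d5$run == r], median_ref(x), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis matches the rank formula and degrades gracefully", {
  # identical groups: no effect, p = 1
  tab <- mk_metrics(rep(c(1, 2, 3), 2), run = rep(1:2, each = 3))
  expect_equal(kruskal_wallis(tab, "m")$p_value, 1)

  # all values identical: degenerate H = 0, p = 1 rather than an error
  same <- mk_metrics(rep(4, 6), run = rep(1:2, each = 3))
  r <- kruskal_wallis(same, "m")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # manual rank oracle on three separated groups
  v <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(1:3, each = 3)
  got <- kruskal_wallis(mk_metrics(v, run = g), "m")
  expect_equal(got$statistic, kw_ref(v, g), tolerance = 1e-12)

  # with ties, still equal to the tie-corrected formula
  set.seed(2)
  vt <- sample(1:4, 30, replace = TRUE)
  gt <- rep(1:3, each = 10)
  expect_equal(kruskal_wallis(mk_metrics(vt, run = gt), "m")$statistic,
               kw_ref(vt, gt), tolerance = 1e-12)

  # two-group case coincides with the normal-approximation rank-sum test
  v2 <- stats::rnorm(24)
  g2 <- rep(1:2, each = 12)
  kw <- kruskal_wallis(mk_metrics(v2, run = g2), "m")
  wt <- stats::wilcox.test(v2[g2 == 1], v2[g2 == 2], exact = FALSE,
                           correct = FALSE)
  expect_equal(kw$p_value, wt$p.value, tolerance = 1e-10)

  # chi-square p approximates the permutation null
  set.seed(4)
  vp <- stats::rnorm(30)
  gp <- rep(1:3, each = 10)
  obs <- kruskal_wallis(mk_metrics(vp, run = gp), "m")
  perm <- replicate(2000, kw_ref(vp, sample(gp)))
  expect_equal(mean(perm >= obs$statistic - 1e-12), obs$p_value,
               tolerance = 0.03)
})

test_that("pairwise tests cover all pairs and adjust with step-up FDR", {
  set.seed(6)
  tab <- mk_metrics(stats::rnorm(40), run = rep(1:5, 8))
  pw <- pairwise_tests(tab, "m")
  expect_equal(nrow(pw), choose(5, 2))
  expect_equal(pw$adjusted_p, bh_ref(pw$p_value), tolerance = 1e-12)
  expect_true(all(pw$adjusted_p >= pw$p_value - 1e-12))

  # single comparison: BH identity at m = 1
  tab2 <- mk_metrics(stats::rnorm(10), run = rep(1:2, 5))
  pw2 <- pairwise_tests(tab2, "m")
  expect_equal(pw2$adjusted_p, pw2$p_value)

  # Brown-Mood variant runs on the same pairs
  bm <- pairwise_tests(tab, "m", method = "brown_mood")
  expect_equal(nrow(bm), choose(5, 2))
  expect_true(all(bm$p_value >= 0 & bm$p_value <= 1))

  # randomized p-vectors: p.adjust use equals the step-up definition
  for (rep in 1:10) {
    p <- stats::runif(sample(3:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_ref(p), tolerance = 1e-12)
  }
})

test_that("the paired library test handles zeros, direction and exactness", {
  pre <- mk_metrics(c(50, 48, 52, 49), "pre_capture")
  post <- pre; post$metric <- "enriched"

  # enriched identical to pre-capture: degenerate, p = 1
  deg <- paired_library_test(rbind(pre, post))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_equal(deg$direction, "none")

  # constant decrease: direction "decrease"
  post2 <- post; post2$value <- post2$value - 10
  dec <- paired_library_test(rbind(pre, post2))
  expect_equal(dec$direction, "decrease")
  expect_true(dec$p_value < 0.2)  # n = 4, exact floor is 2/16

  # exact p equals full 2^n sign enumeration
  set.seed(9)
  for (n in c(6, 9, 12)) {
    pre_n <- mk_metrics(stats::rnorm(n, 50, 5), "pre_capture")
    post_n <- pre_n
    post_n$metric <- "enriched"
    post_n$value <- post_n$value + stats::rnorm(n, -1, 2)
    got <- paired_library_test(rbind(pre_n, post_n))
    ref <- wilcox_exact_ref(post_n$value - pre_n$value)
    expect_equal(got$statistic, ref$V)
    expect_equal(got$p_value, ref$p, tolerance = 1e-12)
  }
})

test_that("Kendall tau-b matches all-pairs counting with its CI and symmetries", {
  x <- 1:8
  expect_equal(tau_test(x, x * 2)$tau, 1)
  expect_equal(tau_test(x, rev(x))$tau, -1)

  set.seed(14)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    x <- sample(1:6, n, replace = TRUE)   # ties on purpose
    y <- x + sample(0:4, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    got <- tau_test(x, y)
    expect_equal(got$tau, tau_b_ref(x, y), tolerance = 1e-12)
    expect_true(got$ci_low <= got$tau && got$tau <= got$ci_high)
    # antisymmetry and monotone-transform invariance
    expect_equal(tau_test(x, -y)$tau, -got$tau, tolerance = 1e-12)
    expect_equal(tau_test(exp(x), y^3)$tau, got$tau, tolerance = 1e-12)
  }
})

test_that("tau correlation pairs metrics with coverage and skips thin strata", {
  set.seed(25)
  n <- 20
  met <- mk_metrics(stats::rnorm(n, 50, 5), "enriched",
                    run = rep(1:2, n / 2))
  diag <- data.frame(sample = met$sample, depth = 100,
                     q2 = met$value * 0.8 + stats::rnorm(n, 0, 2))
  cov <- coverage_q2(diag, "SNV")
  expect_equal(unique(cov$stratum), "SNV_100X")
  res <- tau_correlation(met, cov)
  expect_equal(nrow(res), 1)
  expect_true(res$tau > 0.5)
  expect_equal(res$tau, tau_b_ref(met$value, diag$q2), tolerance = 1e-12)

  thin <- cov[1:2, ]
  expect_warning(out <- tau_correlation(met, thin), "skipping")
  expect_equal(nrow(out), 0)
})

test_that("the tau heatmap export mirrors the results and round-trips", {
  res <- data.frame(metric = c("enriched", "enriched", "conc"),
                    stratum = c("SNV_100X", "SNV_250X", "SNV_100X"),
                    run = NA, n = 20, tau = c(0.45, 0.3, -0.2),
                    p_value = c(0.003, 0.06, 0.2),
                    ci_low = 0, ci_high = 1, stringsAsFactors = FALSE)
  prefix <- file.path(withr::local_tempdir(), "tau")
  out <- heatmap_export(res, prefix)
  expect_equal(out$matrix["enriched", "SNV_100X"], 0.45)
  expect_equal(out$matrix["conc", "SNV_250X"], NA_real_)
  expect_true(all(file.exists(out$paths)))
  back <- utils::read.delim(paste0(prefix, ".tsv"), check.names = FALSE)
  expect_equal(back[["SNV_100X"]], c(0.45, -0.2))

  one <- res[1, ]
  out1 <- heatmap_export(one, file.path(withr::local_tempdir(), "t1"))
  expect_equal(dim(out1$matrix), c(1L, 1L))
})
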