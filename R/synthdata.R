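# Synthetic coverage and metrics simulator with machine-readable ground
# truth. Emulates the two empirically observed exon coverage profile
# types: a high-coverage profile (flat plateau, gradual decay at the
# exon boundaries) and a low-coverage profile (irregular plateau with
# coverage breakoffs starting before the exon boundaries), plus injected
# rectangular drops and run-stratified wet metrics on realistic scales.

#' Simulation configuration
#'
#' All randomness flows through the single integer `seed`; identical
#' configurations produce byte-identical outputs. Defaults describe a
#' well-behaved DNA validation run: plateau depths lognormal around a
#' 648X median (the scale of a high-throughput hybrid-capture panel run),
#' 90% high-coverage exons, 5% depth noise, and 16 samples per
#' preparation across 5 sequencing runs for the metrics layer.
#'
#' @param n_samples Samples in the coverage cohort.
#' @param n_genes,exons_per_gene Panel layout.
#' @param exon_length Length range in bases, sampled uniformly.
#' @param depths Depth-threshold grid of the emitted covdata.
#' @param run_type `"DNA"` or `"RNA"` (sets the plateau default: 648X
#'   for DNA, 80X for RNA, when `plateau_median` is `NULL`).
#' @param high_fraction Fraction of exons with the high-coverage profile.
#' @param plateau_median,plateau_sdlog Lognormal plateau depth across
#'   exons (X-fold).
#' @param sample_sdlog Lognormal per-sample multiplicative factor.
#' @param decay_width Width in bases of the linear boundary-decay ramp at
#'   each exon edge.
#' @param decay_floor Ramp depth at the outermost base, as a fraction of
#'   the plateau.
#' @param noise_sd Gaussian depth noise, as a fraction of the plateau;
#'   integer-rounded, truncated at 0.
#' @param low_scale Range of the plateau scaling factor for low-coverage
#'   exons.
#' @param breakoff_fraction Range of the fraction of a low-coverage exon
#'   lost to boundary breakoffs.
#' @param drops List `count`, `width` (range, bases), `ratio` (range,
#'   fraction of the plateau) describing injected rectangular drops.
#' @param depleted_regions Optional list `n`, `depth`: force `n`
#'   high-coverage exons to a depth between the previous grid threshold
#'   and `depth`, so they fail the MPC rule at `depth` (and above) only.
#' @param depleted_samples Optional list `n`, `depth`, and optionally
#'   `exon_fraction` (default 0.4), `base_fraction` (default 0.3): force
#'   `n` samples to fail the Q1 rule at `depth` but not below it.
#' @param n_per_run,n_runs Metrics layer: samples per preparation and
#'   number of sequencing runs.
#' @param run_effects Optional named list, metric name -> multiplicative
#'   per-run effect vector of length `n_runs` (additive for `delta_cq`).
#' @param seed Integer seed governing all randomness.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 8, n_genes = 25, exons_per_gene = 4,
                       exon_length = c(120, 360),
                       depths = c(5, 10, 50, 100, 250, 500),
                       run_type = c("DNA", "RNA"), high_fraction = 0.9,
                       plateau_median = NULL, plateau_sdlog = 0.35,
                       sample_sdlog = 0.12, decay_width = 10,
                       decay_floor = 0.6, noise_sd = 0.05,
                       low_scale = c(0.05, 0.4),
                       breakoff_fraction = c(0.2, 0.6),
                       drops = list(count = 0, width = c(11, 30),
                                    ratio = c(0.05, 0.25)),
                       depleted_regions = NULL, depleted_samples = NULL,
                       n_per_run = 16, n_runs = 5, run_effects = NULL,
                       seed = 1L) {
  run_type <- match.arg(run_type)
  if (is.null(plateau_median)) {
    plateau_median <- if (run_type == "DNA") 648 else 80
  }
  stopifnot(n_samples >= 1, n_genes >= 1, exons_per_gene >= 1,
            length(exon_length) == 2, exon_length[1] >= 20,
            exon_length[2] >= exon_length[1],
            high_fraction >= 0, high_fraction <= 1,
            plateau_median > 0, plateau_sdlog >= 0, sample_sdlog >= 0,
            decay_width >= 0, decay_floor > 0, decay_floor <= 1,
            noise_sd >= 0, all(low_scale > 0), all(low_scale <= 1),
            all(breakoff_fraction >= 0), all(breakoff_fraction <= 1))
  depths <- sort(unique(as.integer(depths)))
  if (!is.list(drops) || is.null(drops$count)) stop("invalid drop spec")
  if (drops$count > 0) {
    if (drops$width[1] < 1) stop("drop width must be >= 1")
    if (drops$width[2] > exon_length[1] - 2 * decay_width - 4) {
      stop("infeasible drop spec: width can exceed the smallest exon ",
           "interior")
    }
    if (any(drops$ratio <= 0) || any(drops$ratio >= 1)) {
      stop("drop ratio must lie in (0, 1)")
    }
  }
  for (forced in list(depleted_regions, depleted_samples)) {
    if (!is.null(forced)) {
      stopifnot(forced$n >= 1, forced$depth %in% depths)
      if (!any(depths < forced$depth)) {
        stop("forced depletion depth must have a lower grid depth")
      }
    }
  }
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 exons_per_gene = exons_per_gene,
                 exon_length = exon_length, depths = depths,
                 run_type = run_type, high_fraction = high_fraction,
                 plateau_median = plateau_median,
                 plateau_sdlog = plateau_sdlog,
                 sample_sdlog = sample_sdlog, decay_width = decay_width,
                 decay_floor = decay_floor, noise_sd = noise_sd,
                 low_scale = low_scale,
                 breakoff_fraction = breakoff_fraction, drops = drops,
                 depleted_regions = depleted_regions,
                 depleted_samples = depleted_samples,
                 n_per_run = n_per_run, n_runs = n_runs,
                 run_effects = run_effects, seed = as.integer(seed)),
            class = "sim_config")
}

sim_targets <- function(config) {
  n <- config$n_genes * config$exons_per_gene
  gene <- rep(sprintf("G%03d", seq_len(config$n_genes)),
              each = config$exons_per_gene)
  exon <- rep(seq_len(config$exons_per_gene), config$n_genes)
  region_id <- paste0(gene, "_ex", exon)
  chrom <- paste0("chr", ((seq_len(config$n_genes) - 1) %% 22) + 1)
  chrom <- rep(chrom, each = config$exons_per_gene)
  len <- floor(stats::runif(n, config$exon_length[1],
                            config$exon_length[2] + 1))
  start <- integer(n)
  cursor <- stats::setNames(rep(10000L, 22), paste0("chr", 1:22))
  for (i in seq_len(n)) {
    start[i] <- cursor[chrom[i]]
    cursor[chrom[i]] <- cursor[chrom[i]] + len[i] + 500L
  }
  data.frame(chrom = chrom, start = start, end = start + len,
             region_id = region_id, gene = gene, stringsAsFactors = FALSE)
}

ramp_factors <- function(len, width, floor) {
  f <- rep(1, len)
  if (width > 0 && len > 2 * width) {
    edge <- floor + (1 - floor) * (seq_len(width) - 1) / width
    f[seq_len(width)] <- edge
    f[len - seq_len(width) + 1] <- edge
  }
  f
}

# Midpoint between a grid depth and the next lower one: deep enough to
# pass every lower threshold, too shallow to pass the target.
forced_depth_level <- function(depths, depth) {
  prev <- max(depths[depths < depth])
  as.integer(floor((prev + depth) / 2))
}

#' Simulate per-base coverage profiles with ground truth
#'
#' High-coverage exons get a flat plateau with linear decay ramps at the
#' edges plus integer-rounded Gaussian noise; low-coverage exons get a
#' scaled-down irregular plateau with near-zero breakoff segments at the
#' boundaries. Injected rectangular drops, forced region depletions and
#' forced sample depletions are recorded in the returned ground truth.
#' Deterministic under the config seed.
#'
#' @param config A [sim_config()] object.
#' @return List with `profiles` (flat list of [perbase_profile()],
#'   sample-major), `targets` (region table), `truth` (list: `regions`
#'   per-exon profile assignment, `drops`, `depleted_regions`,
#'   `depleted_samples`) and `config`.
#' @export
simulate_perbase <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    targets <- sim_targets(config)
    n_reg <- nrow(targets)
    len <- targets$end - targets$start
    samples <- sprintf("S%02d", seq_len(config$n_samples))

    is_high <- stats::runif(n_reg) < config$high_fraction
    plateau <- stats::rlnorm(n_reg, log(config$plateau_median),
                             config$plateau_sdlog)
    plateau[!is_high] <- plateau[!is_high] *
      stats::runif(sum(!is_high), config$low_scale[1], config$low_scale[2])

    forced_reg <- integer(0)
    if (!is.null(config$depleted_regions)) {
      cand <- which(is_high)
      if (length(cand) < config$depleted_regions$n) {
        stop("not enough high-coverage exons to force depletion")
      }
      forced_reg <- sort(sample(cand, config$depleted_regions$n))
      plateau[forced_reg] <- forced_depth_level(
        config$depths, config$depleted_regions$depth)
    }

    forced_smp <- integer(0)
    smp_exons <- list()
    if (!is.null(config$depleted_samples)) {
      ds <- config$depleted_samples
      ef <- if (is.null(ds$exon_fraction)) 0.4 else ds$exon_fraction
      bf <- if (is.null(ds$base_fraction)) 0.3 else ds$base_fraction
      forced_smp <- sort(sample(seq_len(config$n_samples), ds$n))
      for (s in forced_smp) {
        smp_exons[[as.character(s)]] <-
          sort(sample(seq_len(n_reg), max(1, round(ef * n_reg))))
      }
      chunk_depth <- forced_depth_level(config$depths, ds$depth)
    }

    # injected drops: high, unforced exons x unforced samples
    drop_truth <- NULL
    drop_map <- list()
    if (config$drops$count > 0) {
      elig_r <- setdiff(which(is_high), forced_reg)
      elig_s <- setdiff(seq_len(config$n_samples), forced_smp)
      combos <- expand.grid(r = elig_r, s = elig_s)
      if (nrow(combos) < config$drops$count) {
        stop("infeasible drop spec: more drops than eligible ",
             "exon x sample combinations")
      }
      pick <- combos[sample(nrow(combos), config$drops$count), ,
                     drop = FALSE]
      w <- sample(seq(config$drops$width[1], config$drops$width[2]),
                  nrow(pick), replace = TRUE)
      rt <- stats::runif(nrow(pick), config$drops$ratio[1],
                         config$drops$ratio[2])
      off <- integer(nrow(pick))
      for (k in seq_len(nrow(pick))) {
        lo <- config$decay_width + 2L
        hi <- len[pick$r[k]] - config$decay_width - w[k] - 1L
        off[k] <- if (hi <= lo) lo else sample(seq(lo, hi), 1)
        drop_map[[paste(pick$s[k], pick$r[k])]] <-
          c(off = off[k], width = w[k], ratio = rt[k])
      }
      drop_truth <- data.frame(
        sample = samples[pick$s], region_id = targets$region_id[pick$r],
        chrom = targets$chrom[pick$r],
        start = targets$start[pick$r] + off - 1L,
        end = targets$start[pick$r] + off - 1L + w,
        width = w, ratio = rt, stringsAsFactors = FALSE)
    }

    profiles <- vector("list", config$n_samples * n_reg)
    k <- 0L
    for (s in seq_len(config$n_samples)) {
      forced_exons_s <- smp_exons[[as.character(s)]]
      for (i in seq_len(n_reg)) {
        f <- ramp_factors(len[i], config$decay_width, config$decay_floor)
        if (i %in% forced_reg) {
          # deterministic forcing: no sample factor, no noise
          depth <- as.integer(round(plateau[i] * f))
        } else {
          pl <- plateau[i] * stats::rlnorm(1, 0, config$sample_sdlog)
          nsd <- config$noise_sd * pl * if (is_high[i]) 1 else 3
          depth <- round(pl * f + stats::rnorm(len[i], 0, nsd))
          if (!is_high[i]) {
            bf_tot <- stats::runif(1, config$breakoff_fraction[1],
                                   config$breakoff_fraction[2])
            u <- stats::runif(1)
            lb <- round(bf_tot * u * len[i])
            rb <- round(bf_tot * (1 - u) * len[i])
            if (lb > 0) depth[seq_len(lb)] <-
                round(depth[seq_len(lb)] * stats::runif(lb, 0, 0.1))
            if (rb > 0) depth[len[i] - seq_len(rb) + 1] <-
                round(depth[len[i] - seq_len(rb) + 1] *
                        stats::runif(rb, 0, 0.1))
          }
          dm <- drop_map[[paste(s, i)]]
          if (!is.null(dm)) {
            idx <- seq(dm[["off"]], dm[["off"]] + dm[["width"]] - 1L)
            depth[idx] <- max(0L, as.integer(round(dm[["ratio"]] * pl)))
          }
          if (!is.null(forced_exons_s) && i %in% forced_exons_s) {
            ds <- config$depleted_samples
            bf <- if (is.null(ds$base_fraction)) 0.3 else ds$base_fraction
            cl <- max(1L, round(bf * len[i]))
            cs <- config$decay_width + 5L
            depth[seq(cs, min(len[i], cs + cl - 1L))] <- chunk_depth
          }
          depth <- pmax(0L, as.integer(depth))
        }
        k <- k + 1L
        profiles[[k]] <- perbase_profile(
          targets$chrom[i], targets$start[i], targets$end[i],
          targets$region_id[i], samples[s], depth, gene = targets$gene[i])
      }
    }

    truth <- list(
      regions = data.frame(region_id = targets$region_id,
                           profile = ifelse(seq_len(n_reg) %in% forced_reg,
                                            "forced",
                                            ifelse(is_high, "high", "low")),
                           plateau = plateau, stringsAsFactors = FALSE),
      drops = drop_truth,
      depleted_regions = if (length(forced_reg) > 0) {
        data.frame(region_id = targets$region_id[forced_reg],
                   depth = config$depleted_regions$depth,
                   stringsAsFactors = FALSE)
      },
      depleted_samples = if (length(forced_smp) > 0) {
        data.frame(sample = samples[forced_smp],
                   depth = config$depleted_samples$depth,
                   stringsAsFactors = FALSE)
      })
    list(profiles = profiles, targets = targets, truth = truth,
         config = config)
  })
}

#' Simulate a covdata table from per-base profiles
#'
#' Counts are computed exactly from the simulated per-base profiles by
#' direct threshold counting, so the region-level and base-level views
#' describe the same world and the covdata invariants (count <= length,
#' counts non-increasing in depth) hold by construction.
#'
#' @param config A [sim_config()] object.
#' @return List: `covdata` ([covdata()] object), `perbase` (profiles),
#'   `targets`, `truth`, `config`.
#' @export
simulate_covdata <- function(config) {
  pb <- simulate_perbase(config)
  n_reg <- nrow(pb$targets)
  samples <- unique(vapply(pb$profiles, `[[`, "", "sample"))
  counts <- array(0, dim = c(n_reg, length(config$depths),
                             length(samples)))
  k <- 0L
  for (s in seq_along(samples)) {
    for (i in seq_len(n_reg)) {
      k <- k + 1L
      depth <- pb$profiles[[k]]$depth
      counts[i, , s] <- vapply(config$depths,
                               function(d) sum(depth >= d), 0)
    }
  }
  cd <- covdata(pb$targets, config$depths, counts, samples)
  list(covdata = cd, perbase = pb$profiles, targets = pb$targets,
       truth = pb$truth, config = config)
}

metric_defs <- function() {
  d <- function(metric, nucleic, dist, location, scale) {
    data.frame(metric = metric, nucleic = nucleic, dist = dist,
               location = location, scale = scale, stringsAsFactors = FALSE)
  }
  rbind(
    d("conc", "DNA", "lognormal", 17.1, 0.60),
    d("a260_280", "DNA", "normal", 1.97, 0.15),
    d("a260_230", "DNA", "lognormal", 0.67, 0.50),
    d("delta_cq", "DNA", "normal", 0.3, 1.5),
    d("frag_qc", "DNA", "normal", 232, 30),
    d("pre_capture", "DNA", "normal", 48.7, 5),
    d("median_insert_size", "DNA", "normal", 113, 16),
    d("coverage_mad", "DNA", "normal", 0.161, 0.047),
    d("median_target_coverage", "DNA", "lognormal", 648, 0.45),
    d("conc", "RNA", "lognormal", 66, 0.70),
    d("a260_280", "RNA", "normal", 1.96, 0.10),
    d("a260_230", "RNA", "normal", 1.36, 0.45),
    d("dv200", "RNA", "normal", 63.7, 16),
    d("pre_capture", "RNA", "normal", 51, 6))
}

#' Simulate a wet/sequencing metrics table with ground truth
#'
#' Per-metric draws around configured medians (lognormal for scale-like
#' metrics, Gaussian for ratio/size-like metrics), multiplied by optional
#' per-run effects (additive for `delta_cq`, whose sign is meaningful).
#' Enriched library values are generated as paired fractions of the
#' pre-capture values, so the pre-capture vs enriched comparison shows a
#' median decrease by construction. Deterministic under the config seed.
#'
#' @param config A [sim_config()] object; uses `n_per_run`, `n_runs`,
#'   `run_effects`, `seed`.
#' @param enriched_ratio Named median enriched/pre-capture ratios.
#' @return List: `metrics` (long data frame `sample`, `run`, `nucleic`,
#'   `metric`, `value`), `truth` (`metric_medians` per metric x run),
#'   `config`.
#' @export
simulate_metrics <- function(config,
                             enriched_ratio = c(DNA = 0.38, RNA = 0.128)) {
  stopifnot(inherits(config, "sim_config"))
  defs <- metric_defs()
  local_seed(config$seed, {
    rows <- list(); med <- list()
    for (nt in c("DNA", "RNA")) {
      dn <- defs[defs$nucleic == nt, , drop = FALSE]
      for (r in seq_len(config$n_runs)) {
        ids <- sprintf("%s_R%d_S%02d", nt, r, seq_len(config$n_per_run))
        vals <- list()
        for (i in seq_len(nrow(dn))) {
          m <- dn$metric[i]
          eff <- 1
          if (!is.null(config$run_effects[[m]])) {
            eff <- config$run_effects[[m]][r]
          }
          n <- config$n_per_run
          v <- if (dn$dist[i] == "lognormal") {
            dn$location[i] * exp(stats::rnorm(n, 0, dn$scale[i])) * eff
          } else if (m == "delta_cq") {
            dn$location[i] + (eff - 1) + stats::rnorm(n, 0, dn$scale[i])
          } else {
            dn$location[i] * eff + stats::rnorm(n, 0, dn$scale[i])
          }
          if (m == "coverage_mad") v <- pmax(v, 0.005)
          if (m == "dv200") v <- pmin(pmax(v, 0), 100)
          if (m == "a260_230") v <- pmax(v, 0.03)
          vals[[m]] <- v
          tm <- if (m == "delta_cq") dn$location[i] + (eff - 1) else
            dn$location[i] * eff
          med[[length(med) + 1L]] <- data.frame(
            nucleic = nt, metric = m, run = r, true_median = tm,
            stringsAsFactors = FALSE)
        }
        ratio <- unname(enriched_ratio[nt]) *
          exp(stats::rnorm(config$n_per_run, 0, 0.4))
        vals[["enriched"]] <- vals[["pre_capture"]] * ratio
        med[[length(med) + 1L]] <- data.frame(
          nucleic = nt, metric = "enriched", run = r,
          true_median = dn$location[dn$metric == "pre_capture"] *
            unname(enriched_ratio[nt]),
          stringsAsFactors = FALSE)
        for (m in names(vals)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = ids, run = r, nucleic = nt, metric = m,
            value = vals[[m]], stringsAsFactors = FALSE)
        }
      }
    }
    list(metrics = metrics_table(do.call(rbind, rows)),
         truth = list(metric_medians = do.call(rbind, med)),
         config = config)
  })
}
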