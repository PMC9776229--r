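---
title: "Coverage diagnostics for targeted sequencing panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage diagnostics for targeted sequencing panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcov)
```

## The problem

Hybrid-capture gene panels used in clinical oncology call variants only
where sequencing depth supports them. Global coverage metrics (mean
target coverage, percent of target at 100X) can look excellent while
individual exons — or narrow stretches inside exons — are effectively
unsequenced, and every such stretch is a potential false-negative
variant call. `panelcov` implements a region- and base-level diagnostic
layer that makes these blind spots explicit, together with the
nonparametric statistics used to monitor wet-lab and sequencing metrics
across validation runs.

## The model and its statistics

The input is a *covdata* table: for every target region (exon) and every
sample, the number of bases covered at or above each threshold of a
depth grid (5, 10, 50, 100, 250, 500X in full; DNA runs are judged at
50–500X, RNA runs at 5–50X, reflecting the much lower RNA input
amounts). Counts are validated against two invariants — a count never
exceeds the region length, and counts are non-increasing in depth —
because violations of either indicate an upstream depth-counting bug
rather than a biological signal.

From counts the package derives:

* **Percent coverage** `p = 100 · count / (end − start)`, per (region,
  sample, depth).
* **MPC**, the median of `p` across samples, per (region, depth). The
  median (mean of the central pair for even cohort sizes) is used
  because single failed samples should not drag down a run-level region
  verdict.
* **Run rule**: a run should maximise the number of grid depths whose
  MPC summary reaches 75%. MPC is per-region, so a run-level summary
  needs an aggregation over regions; the regionwise *median* is the
  default reading, with `mean` and `fraction` (percent of regions at or
  above the threshold) selectable, since the rule's aggregation is a
  genuinely open design choice.
* **Sample rule**: a sample is flagged at depth `D` when the first
  quartile of its per-exon `p` distribution falls below 75% — i.e. when
  fewer than 75% of its exons are at least 75% covered at `D`. Quartiles
  use linear interpolation between order statistics (type 7), the
  default convention of this statistical environment.
* **Blacklists**: a region with MPC strictly below 75% at a depth is
  written to that depth's blacklist BED. Threshold comparisons are
  inclusive everywhere (exactly 75 passes, exactly 0.21 complies),
  mirroring how the rules are stated; blacklisting therefore uses the
  strict complement. Because `p` is non-increasing in depth, blacklists
  are nested: anything blacklisted at 250X is blacklisted at 500X.
* **Coverage MAD**: per-region mean depths for one sample, normalised by
  their median; the raw median absolute deviation (no 1.4826 consistency
  constant) of the normalised values, compliant at ≤ 0.21. The linear,
  median-normalised definition is this package's declared definition —
  vendor pipelines do not document whether theirs operates on log-scale
  fold changes — and it is scale-invariant, so it measures uniformity
  only.

### Base-level drop detection

Region-level percentages cannot localise a failure. The drop scanner
works on per-base depth tracks (run-length encoded BED4, the native
output shape of standard depth counters): an exon is *eligible* when its
per-base median depth reaches `eligibility_depth` (default 100X); a
*drop* is a maximal run of at least `min_width` (default 10) consecutive
bases each strictly below `drop_ratio` (default 0.5) times the exon
median. The defaults are this package's operational definition of
"narrow drop inside a highly covered exon" — no published constant
exists for them — and all three are exposed in configuration and CLI.
Drops are clipped at exon boundaries, which deliberately excludes the
gradual boundary decay that healthy capture profiles show outside the
exon proper. The exon median is computed from the per-base profile of
that exon and sample, not from covdata counts, because counts cannot
localise anything.

### QC statistics layer

Wet and sequencing metrics (concentrations, absorbance ratios, DV200,
ΔCq, fragment sizes, library yields) are compared across sequencing runs
with the Kruskal–Wallis test, followed by all pairwise Mann–Whitney (or
Brown–Mood median) tests under Benjamini–Hochberg FDR control; BH is the
default because "false discovery rate" without qualification denotes the
step-up procedure, with Benjamini–Yekutieli selectable. Pre-capture vs
enriched library yields are compared with the Wilcoxon signed-rank test
(zeros dropped before ranking, the classic convention; a signed-zero
variant sits behind a flag), exact for n ≤ 25 without ties. Metric–
coverage association uses Kendall's tau-b (tie-corrected), pairing each
sample's metric value with its median exon percent coverage (Q2) per
variant type and depth; the 95% CI uses the asymptotic null standard
error `sqrt(2(2n+5)/(9n(n−1)))`, a declared approximation since no CI
formula is canonical for tau. All tests are two-sided at 0.05.

Two compliance-rule presets are shipped and never merged, because the
documented sources genuinely disagree (the sample-inclusion window for
260/280 absorbance is 1.6–1.8 for DNA, while the run-table annotation
says "compliant if > 2"): `"section21"` carries the inclusion and
run-level thresholds (DV200 ≥ 20%, ΔCq ≤ 5, absorbance windows, median
insert size ≥ 70, coverage MAD ≤ 0.21), `"table1"` the per-metric table
annotations.

## What the simulator emulates

`sim_config()` + `simulate_perbase()` / `simulate_covdata()` /
`simulate_metrics()` generate a self-consistent world: covdata counts
are derived from the simulated per-base profiles by direct threshold
counting, never sampled independently, so region-level and base-level
modules always agree.

Two empirical coverage-profile types drive the generator:

* **high-coverage**: a flat plateau (lognormal across exons, median
  648X for DNA — the scale of a high-throughput panel run — times a
  lognormal per-sample factor), linear decay ramps at the exon edges,
  and integer-rounded Gaussian noise (default 5% of the plateau);
* **low-coverage**: the plateau scaled to 5–40%, noisier, with
  near-zero breakoff segments entering from the exon boundaries.

Defaults: 8 samples, 100 exons of 120–360 bp, 90% high-coverage exons,
RNA plateau median 80X; the metrics layer draws 16 samples per
preparation across 5 runs, lognormal or Gaussian per metric around
medians on the scale of real validation tables, with enriched library
yields generated as a paired fraction (median 0.38 for DNA, 0.128 for
RNA) of pre-capture yields, so the paired test sees a genuine median
decrease.

Ground-truth forcing knobs exist for testability: `depleted_regions`
pins chosen exons to the midpoint between two grid depths (without
per-sample noise, so recovery is exact by construction), and
`depleted_samples` inserts a constant-depth chunk into a fraction of a
sample's exons so that exactly that sample fails the Q1 rule at exactly
the forced depth.

What the simulator does **not** model: read sampling (noise is Gaussian,
not binomial/Poisson from reads), GC- or mappability-driven dropout
structure, fragment-length effects, or any sequencing-error process.
Passing tests on simulated data therefore demonstrate the correctness of
the diagnostics' logic and algebra, not the field performance of a
specific assay.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED convention) everywhere,
  including covdata input; upstream 1-based tables must be shifted. This
  is stated prominently because depth-counter outputs differ.
* Gene symbols are the region-id prefix before the first `_`
  (configurable separator); region-id syntax is not standardised.
* Duplicate region keys within a sample are a hard error — silent
  aggregation could mask panel-design bugs. Non-monotone depth counts
  are an error, downgradeable to a warning with `lenient = TRUE`.
* A header-only covdata file is an empty table, not an error; an empty
  per-base profile is an error; an ineligible exon yields an empty drop
  set, not an error.
* Kruskal–Wallis on identical values returns H = 0, p = 1 (the tie
  correction would otherwise divide by zero); an all-zero-difference
  paired test returns a degenerate record with p = 1.
* Blacklist BED scores are `round(10 · MPC)`, drop scores
  `round(1000 · (1 − ratio))`, both clipped to the BED score range.

## Problem sizes used in the test-suite experiments

The packaged experiments run at desk scale, chosen to finish in seconds
while keeping the statistical checks meaningful: 1000 random exons for
the percent-coverage oracle, 200 exons with one injected drop each for
the recall experiment (injection at ratio ≤ 0.25 and width ≥ 11 against
a detector at 0.5/10, i.e. a ≥2× ratio margin and ≥1 base width margin),
and 500 replicates of 5 × 16 null samples for the Kruskal–Wallis
calibration, whose rejection rate is required to sit within 5% ± 2%
(about two Monte-Carlo standard errors).

## Known limitations

* The run-level aggregation of MPC and the drop criterion are declared
  definitions, not community standards; both are configurable and both
  should be reported alongside any results.
* The tau CI uses the null asymptotic standard error, which is
  conservative for |tau| near 1.
* Blacklisting is cohort-level (MPC); a single catastrophic sample is
  visible only through the Q1 rule, by design.
* The simulator's Gaussian noise slightly underestimates the dispersion
  of true read-sampling noise at low depth.
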