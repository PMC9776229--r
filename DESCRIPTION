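Package: panelcov
Title: Coverage Diagnostics and Quality-Control Statistics for Targeted
    Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Diagnostics for hybrid-capture targeted sequencing panels
    based on per-region depth-threshold count tables. Computes exon
    percent coverage and the median percent coverage (MPC) statistic,
    per-sample quartile diagnostics with run- and sample-level quality
    rules, low-coverage region blacklists, base-level detection of
    narrow coverage drops inside well-covered exons, and the coverage
    MAD uniformity metric used for copy-number calling regions. A
    companion statistics layer provides descriptive summaries of wet-lab
    and sequencing metrics, compliance flagging against documented
    thresholds, Kruskal-Wallis and pairwise rank tests with false
    discovery rate adjustment, paired library-yield testing, and
    Kendall tau-b correlation between laboratory metrics and coverage.
    A synthetic coverage and metrics simulator with machine-readable
    ground truth makes the whole workflow testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
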