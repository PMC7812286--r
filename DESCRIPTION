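Package: dnbtip
Title: Dynamic Network Biomarker Analysis of Tipping Points in
    Time-Series Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects pre-transition (tipping-point) states in time-series
    transcriptome experiments with the dynamic network biomarker (DNB)
    framework: control-adjusted per-timepoint statistics, co-expression
    module discovery, the composite index CI = PCC_in * SD_in / PCC_out,
    and a permutation test for the tipping call. Includes a synthetic-data
    generator that emulates a treated/control time-course design with a
    planted DNB module, a Welch-t differential-expression stand-in with
    fold-change and FDR thresholds, hypergeometric gene-set
    over-representation, network-based ranking of candidate driver genes,
    and a dimensionless mutual-repression (toggle switch) model with
    fixed-point, bifurcation and stochastic analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    igraph,
    deSolve
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
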