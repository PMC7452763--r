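Package: epgtools
Title: Quantifying DNA Degradation from Capillary Electrophoresis
    Electropherograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing DNA degradation and sequencing readiness
    from Fragment Analyzer style electropherogram exports. Merges traces
    across instrument runs with size-binning rules, computes per-treatment
    mean traces with confidence bands, quantifies high-molecular-weight
    (HMW, >20 kbp) DNA content by windowed area under the curve with
    max-referenced standardization and DESS/ETOH scale factors, derives a
    Genomic Quality Number style fragmentation score, and fits the full
    factorial ANOVA over a preservation-treatment design. Includes a
    synthetic electropherogram generator emulating a 200-sample
    preservation experiment (lognormal size-component mixture,
    treatment-dependent exponential HMW decay, per-fish amplitude effects,
    run-specific size-axis jitter, additive detector noise) so the whole
    pipeline runs and is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
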