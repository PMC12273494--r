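Package: oxkin
Title: Weibull Lag-Phase Kinetics and Antioxidant Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing spectrophotometric lipid-oxidation kinetics
    from microplate assays. Fits a two-parameter Weibull decay model to
    reduced absorbance curves by nonlinear least squares, extracts the lag
    phase (induction period) as the time at which the Weibull probability
    density reaches a fixed rate threshold, and propagates parameter
    uncertainty to lag-phase confidence intervals by Monte-Carlo simulation.
    Quantifies antioxidant combination effects through the combination factor
    (ratio of the combination lag phase to the sum of the solo lag phases),
    classifies interactions as synergistic, additive or antagonistic, and
    assigns qualitative trend types across molar-ratio series. Includes a
    synthetic assay generator emulating plate-reader absorbance decay,
    summary-statistic hypothesis tests (one-way ANOVA with Tukey HSD, paired
    and independent t-tests computed from means, standard deviations and
    sample sizes), long/wide table readers and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
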