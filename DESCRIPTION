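Package: floralreg
Title: Regression Modeling of Floral Induction by FT-Like Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Condition-stratified regression models of meristem identity gene
    activation by FT-like florigen genes, developed for qRT-PCR time courses of
    narrow-leafed lupin (Lupinus angustifolius) under photoperiod, vernalization
    and time-of-day treatments. Provides a model family ranging from a single
    cumulative FT input to gene-specific, nonlinear and time-dependent regulator
    terms; in-silico regulator knockouts that emulate loss-of-function mutants;
    a block-weighted cost function minimized by Nelder-Mead with an exact
    weighted-least-squares oracle; parametric resampling of mean +/- s.d.
    expression data; small-sample corrected AIC model comparison; paired
    hypothesis tests of fit-quality distributions; block-level defect
    diagnostics; and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
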