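Package: mocasim
Title: Simulated Evaluation of Age-Education Correction for Cognitive
    Screening Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo simulation pipeline for studying how
    regression-based age-education correction of Montreal Cognitive
    Assessment (MoCA) scores affects discrimination (AUC), sensitivity,
    and specificity of cognitive screening, overall and within
    age-education strata, in a model of the Italian resident population
    aged 55 to 89.  Ships a machine-readable joint distribution of sex,
    age group, education, and cognitive status; generates raw scores from
    published normative equations with status offsets and Gaussian
    residuals; fits the normative correction on healthy development
    samples; determines marginal cutoffs at preselected operating points;
    and aggregates replicated develop-then-validate experiments into
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
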