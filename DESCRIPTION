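Package: epiaccel
Title: Epigenetic Clock Age Acceleration Analysis for DNA Methylation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Applies linear CpG-methylation clocks with a calibrated age
    transform to Illumina-style beta-value matrices, quantifies epigenetic age
    acceleration in case/control cohorts (control-anchored residuals and the
    years-of-acceleration ratio from a multivariate regression), fits a
    random-intercept model for sibship-structured designs, estimates blood
    cell-type composition by constrained projection onto a signature matrix
    with a reference-free latent-factor alternative and a simplified mediation
    test, and computes per-CpG marginal statistics with signed -log10 P
    conventions, quadrant calls, cross-dataset preservation and meta-analysis.
    Ships a seeded synthetic methylation-cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
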