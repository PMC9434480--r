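Package: liabsem
Title: Shared and Disorder-Differentiating Genetic Liability from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the common-variant liabilities of three psychiatric
    disorders (schizophrenia, bipolar disorder, major depressive disorder)
    into one shared component and three disorder-differentiating components
    using a common-factor genomic structural equation model fitted to LD
    score regression estimates of genetic covariance, with per-variant
    shared and differentiating effect estimates, LD-clumped unthresholded
    polygenic risk scores, and ordinal/logistic association analysis of
    bipolar-disorder symptom dimensions. Includes a liability-threshold
    case-control simulator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
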