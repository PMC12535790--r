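Package: metspectrum
Title: Metabolic Syndrome Spectrum Risk Scoring and Validation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a 23-item weighted risk score that places adults on a
    metabolic syndrome (MetS) risk spectrum with banded risk categories, the
    established IDF, NCEP-ATP III and WHO MetS classifiers with South Asian
    cutoffs, the triglyceride-glucose (TyG) insulin-resistance index,
    sample-size and power calculators (Fisher-z correlation design and
    noncentral-F one-way ANOVA design), known-groups validation statistics
    (one-way ANOVA with Tukey HSD and eta-squared, chi-square, Pearson
    correlation with Fisher-z intervals), psychometric reliability statistics
    (Cronbach's alpha, Cohen's kappa, corrected item-total correlations, ROC
    AUC with DeLong intervals), and a calibrated synthetic-cohort generator
    with a single latent severity factor, so the full develop-score-validate
    workflow can be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
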