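Package: hbnet
Title: Estimating Postoperative Facial-Nerve Function from Intraoperative
    EMG Traintime
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating postoperative House-Brackmann facial-palsy
    grades after vestibular schwannoma surgery from intraoperative
    free-running EMG traintime, tumor size (Koos grade) and preoperative
    function. Provides a synthetic cohort generator emulating a 200-patient
    study structure, A-train traintime feature sets with optional cluster
    correction, a single-hidden-layer feed-forward network trained by
    Levenberg-Marquardt with a multinomial logistic-regression baseline, a
    bootstrap evaluation engine (repeated random 75/25 splits, chi-squared
    concordance, Cramer's V, surrogate permutation null with two-sample
    Kolmogorov-Smirnov comparison, Koos and intermediate-nerve subgroup
    analyses), and conventional association statistics (Spearman and partial
    Spearman rank correlations, chi-squared independence, subgroup linear
    models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
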