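Package: irboostSH
Title: Multi-View Boosting with Adversarial Bandits for Incomplete Views
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-class classification from multiple, possibly incomplete,
    feature views of the same samples, as arise in microbiome studies where
    16S amplicon and shotgun tables, or tables produced by different
    preprocessing pipelines, cover overlapping but unequal sets of
    individuals. Implements a boosting procedure that maintains a single
    instance-weight distribution shared across views and, at each iteration,
    selects one winning view with an adversarial multi-armed bandit
    (an exponentially weighted average forecaster with importance-weighted
    rewards); samples absent from the winning view contribute neither to the
    weighted edge nor to the weight update. Includes the binary complete-view
    predecessor algorithm, frequency- and prevalence-based view construction
    from OTU tables, mean-imputation and feature-concatenation baselines, a
    leakage-free cross-validation harness with macro-averaged metrics, and
    Wilcoxon signed-rank comparisons with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ranger,
    rpart,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
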