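Package: regsig
Title: Resistance Gene Signatures from Cell Line Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds resistance gene signatures (REGS) for chemotherapeutic
    agents from in vitro dose-response screens and baseline gene expression
    of cancer cell lines, and evaluates them in patient cohorts. Dose-response
    plates are summarised by the area under the positive part of a
    growth-rate-based dose-response curve (AUC0) with bootstrap confidence
    intervals; expression panels are harmonised by probe-set collapsing,
    median centring and variance matching; per-drug elastic-net classifiers
    and predictors are trained with cross-validated mixing and shrinkage
    parameters; per-drug outputs are fused into a multidrug score by the
    odds-product (Graham) formula or the geometric mean; and scores are
    evaluated against censored survival endpoints with Cox proportional
    hazards models, Kaplan-Meier curves, restricted cubic splines and
    inverse-probability-of-censoring-weighted time-dependent ROC curves.
    A synthetic-data generator emulates the laboratory and clinical designs
    so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    survival,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
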