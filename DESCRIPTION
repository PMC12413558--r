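Package: planeqc
Title: Quality Control of the Midsagittal Plane in Dynamic Pelvic-Floor Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides, from per-frame organ-segmentation probability maps of a
    dynamic transperineal ultrasound video, whether the midsagittal plane (and
    each of eight pelvic organs) was correctly captured. Provides a synthetic
    cohort simulator emulating the output of an upstream segmentation network,
    per-frame confidence and bounding-box feature extraction, sliding-window
    aggregation into tabular datasets, per-organ gradient-boosted classifiers
    tuned by grouped k-fold random search, and the inter-rater concordance
    statistics (Cohen's kappa with 95% CI and agreement bands, exact McNemar
    test, t-based confidence intervals) used to validate verdicts against
    human examiners.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    rhdf5,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
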