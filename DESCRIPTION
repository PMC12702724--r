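Package: cpetentropy
Title: Sample Entropy Analysis of Breath-by-Breath Cardiopulmonary
    Exercise Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for complexity analysis of breath-by-breath
    cardiopulmonary exercise testing (CPET) data in pediatric cohorts.
    Implements moving-window and work-rate-based artifact rejection,
    first-differencing and standardization with Augmented Dickey-Fuller
    stationarity screening under Holm-Sidak correction, Sample Entropy
    (SampEn) with an exact brute-force reference implementation and
    penalized (m, r) parameter selection, pre/post test-midpoint
    segmentation with age and sex grouping, and robust Bayesian group
    comparison via a Student-t likelihood with posterior
    direction-of-effect probabilities. Includes a synthetic ramp-CPET
    cohort generator with controllable signal complexity so the full
    pipeline can be exercised without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
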