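Package: neurocausal
Title: Temporal Causal Structure of Brain and Systemic Physiology from
    Intensive-Care Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning per-patient temporal causal structure from
    minute-resolution multimodality monitoring data, as collected in
    neurological intensive care after subarachnoid hemorrhage. Provides a
    seeded synthetic-cohort generator with planted lagged cause-effect
    relationships and ICU-style missingness mechanisms; preprocessing (minute
    averaging, plausibility filtering, cerebral perfusion pressure derivation,
    phase splitting, and data-characteristics profiling including a KPSS
    nonstationarity screen); FLk-NN imputation combining an iterative Fourier
    reconstruction with a lagged k-nearest-neighbour estimator under a
    30-minute gap cap; discretization of physiologic channels into clinical
    LOW/NORMAL/HIGH states; window-based causal significance (epsilon-average)
    inference with per-patient empirical-null significance testing; and
    population aggregation with k-means phenotyping via the gap statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
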