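Package: trustdyn
Title: Simulating and Modeling Operator Trust Dynamics from Multimodal
    Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A pipeline for estimating an operator's moment-to-moment trust
    in an autonomous teammate from multimodal physiological and behavioral
    data. Provides a synthetic study generator that emulates a
    human-autonomy-teaming protocol (ECG, electrodermal activity,
    respiration, 19-channel EEG, 20-channel fNIRS, and eye tracking over
    45-second epochs, with embedded task-interaction measures and operator
    background variables), signal cleaning and event detection for each
    stream, a versioned feature dictionary with hierarchical imputation,
    two-round relaxed-LASSO stability selection with ordinary least
    squares refitting under anti-overfitting constraints, and
    leave-one-trial-out-per-session Monte-Carlo cross-validation of the
    fitted trust models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
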