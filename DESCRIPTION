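Package: evcddm
Title: Attention Allocation and Choice in Two-Attribute Perceptual
    Decisions via the Expected Value of Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for rewarded two-attribute
    random-dot decision tasks in which observers weigh motion and color
    evidence under asymmetric rewards.  Implements the attention-weighted
    drift-diffusion model of choice and response time, the Expected Value
    of Control (EVC) objective that trades reward rate against an
    exponential cost of attentional intensity (optimized by exhaustive
    grid search), a 3-down/1-up psychophysical calibration staircase with
    its four termination criteria, generators for synthetic cohorts
    (trialwise behavior and region-of-interest beta series with
    configurable encoding weights), and two-stage (per-participant then
    group) regression analyses used as parameter-recovery tests:
    choice/RT regressions on signed coherence, psychometric tables,
    trial-history effects, encoding-model fits, attribute weight-ratio
    tests, rostrocaudal interaction contrasts, and neural-behavioral
    coupling.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
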