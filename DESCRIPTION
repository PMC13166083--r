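Package: loglira
Title: Suppression of Intracortical Microstimulation Artifacts by
    Logarithmic Piecewise-Linear Interpolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-trial suppression of electrical stimulation artifacts in
    extracellular recordings, specialised for recovering short-latency evoked
    spikes. Each artifact is estimated by piecewise-linear interpolation over a
    logarithmically spaced grid after dynamic blanking (with amplifier
    saturation handling), and deterministic residual ("secondary") artifacts
    are removed by clustering the post-blanking windows across trials and
    subtracting cluster means. The package also ships a semisynthetic
    benchmark for evaluating such algorithms: synthetic basal activity with
    known spike times, per-channel artifact template dictionaries, inter
    artifact interval resampling by kernel density estimation, snippet
    synthesis, reference baseline suppressors (dynamic averaging, global
    polynomial fitting), and evaluation metrics (RMSE, jitter-matched
    false positives/negatives, zero-lag spike-train cross-correlation, PSTH).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    MASS,
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
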