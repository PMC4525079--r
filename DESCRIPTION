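Package: whisktouch
Title: Spike-Train Analysis of Active Whisker Touch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-unit spike trains recorded in the
    barrel cortex during active whisker-mediated object localization.
    Decomposes whisker kinematics into whisking phase and amplitude
    (Butterworth bandpass plus analytic signal), segments behavioral
    epochs, computes touch-aligned spike metrics (peri-contact histograms,
    onset latency, cosine phase-tuning fits), attributes spikes to touch
    and whisking phase with shuffle-based chance curves, quantifies
    stimulus-conditioned spike-count variability (Fano factors, binomial
    minimum bounds, density-based touch grouping, refractory-Poisson
    nulls), and runs resampling-based population-decoding simulations of
    touch presence, touch time and whisking phase.  Includes a calibrated
    generator of synthetic behavioral sessions with per-spike ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
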