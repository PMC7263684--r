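Package: ssvepscreen
Title: Harmonic Analysis and Synergy Statistics for Steady-State Visual
    Evoked Potential Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for steady-state visual evoked potential
    (SSVEP) recordings from the fly eye in genetic modifier screens.
    Synthesizes contrast-flicker stimuli, simulates voltage responses with a
    compressive photoreceptor nonlinearity and a quadratic lamina stage,
    decomposes recorded traces into first- and second-harmonic amplitudes
    (1F1, photoreceptors; 2F1, lamina neurons) by FFT with repeat averaging
    and noise-floor estimation, builds per-fly contrast-response functions,
    and computes screen-level genetic-interaction statistics: synergy
    coordinates (X, Y), the synergy-spectrum regression with residual
    classification, Fisher-exact annotation enrichment, the
    lamina-versus-photoreceptor signaling regression with leave-one-out
    outlier detection, and ANOVA with Monte-Carlo Dunnett many-to-one
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
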