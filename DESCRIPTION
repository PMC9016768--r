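Package: txtlperceptron
Title: Simulation and Analysis of a Cell-Free Riboregulator Perceptron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mechanistic modelling and analysis toolkit for cell-free
    transcription-translation (TXTL) perceptron circuits built from toehold
    switch riboregulators. Provides a deterministic ODE simulator of batch
    TXTL reactions (toehold activation with crosstalk, lumped
    transcription/translation resource pools, sigma-factor competition for
    core RNA polymerase, and anti-sigma28 molecular titration), a
    plate-reader emulator producing replicated noisy time courses, rudimentary
    weighted-sum-operation models with scaling-factor least-squares fitting,
    a thresholded perceptron classification layer realizing OR/MAJORITY/AND
    input-count logic, and the accompanying statistical tests (Welch's t,
    one-way ANOVA, one-sided t against a threshold, Grubbs outlier test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
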