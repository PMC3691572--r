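Package: starchdiv
Title: Analog Arithmetic-Division Kinetics of Night-Time Starch Degradation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemical-kinetic models of how Arabidopsis leaves set their
    night-time starch degradation rate by arithmetically dividing starch
    content by the expected time to dawn. Implements the clock-controlled
    T-molecule signal for both division mechanisms, exact piecewise analytic
    starch solutions and their reduced ODEs, the full mass-action reaction
    network used to verify the quasi-steady-state reduction, relative-error
    least-squares fitting by simulated annealing within published parameter
    bounds, degradation-rate statistics with propagated standard errors
    (night-time light interruption test, normalized rate ratio R with
    one-tailed z-tests), and a synthetic-experiment generator that emulates
    early/normal/late nights, night-time light interruptions and multi-day
    recovery from prolonged darkness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
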