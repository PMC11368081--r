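Package: jumpsim
Title: Simulation and Correction of Flight-Time Jump Height Estimation Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the error made by the flight-time method of vertical
    jump height estimation when the ankle is more dorsiflexed at landing than
    at takeoff. A stature-scaled four-segment body model (foot, shank, thigh,
    head-arms-trunk) pivoting at the tiptoes gives the whole-body centre of
    mass drop between takeoff and landing; closed-form ballistic flight
    equations turn that drop into inflated flight times, overestimated jump
    heights and percentage errors over a factorial grid of statures, ankle
    position changes and jump heights. An anthropometric correction equation
    based on the tiptoe-to-ankle distance recovers the true jump height from
    the measured flight time. Includes a command-line interface, tidy tabular
    results, ggplot2 error-surface plots and broom-style model summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
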