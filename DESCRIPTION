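Package: ratecircuit
Title: Firing-Rate Models of Cortical Microcircuits with Three Interneuron Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear firing-rate models of the canonical cortical microcircuit
    formed by excitatory cells and PV, SST and VIP interneurons. Provides the
    smoothed threshold-linear f-I curve, background-current calibration to a
    target baseline, explicit-Euler rate dynamics, and the steady-state linear
    response matrix M = (D - W)^-1 used to classify disinhibition versus
    response-reversal regimes (the paradoxical sign flip of the SST response to
    VIP-targeted top-down modulation) and the inhibition-stabilized-network
    condition. Includes analytic onset derivatives for transient responses, a
    random unit-level network expansion with Bernoulli connectivity, a mouse-V1
    condition battery (darkness, gray screen, size-varying gratings, with and
    without locomotion) with connectivity-robustness checks, rejection sampling
    of sign-structured connectivity matrices, and tidy/ggplot2 interfaces.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
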