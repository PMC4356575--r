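Package: tpvillage
Title: Personality-Driven Agent-Based Simulation of Cooperation in a
    Commons Dilemma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the evolution of cooperation in a village of 150
    agents sharing a limited resource, where each agent carries one of
    seven time-perspective personality profiles with its own interaction
    rules (policing, offering to cooperate, tempting to defect).
    Ships the cross-cultural distribution of the seven profiles for 24
    country samples, runs seeded replicate simulations of the daily
    dynamics, fits the exponential saturation curve
    y(d) = C + B*exp(-d*F) to the equilibrium cooperation level, and
    derives a per-country cooperation index that can be correlated with
    user-supplied socio-economic indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
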