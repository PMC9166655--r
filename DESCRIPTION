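Package: pleiosim
Title: Multilevel Selection Dynamics of Cooperation and Pleiotropy in
    Cellular Groups
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the evolution of cooperation and pleiotropic genetic
    architectures in age-structured populations of cellular groups. Cells
    carry three binary traits (a costly cooperative trait, a privately
    beneficial trait, and a pleiotropy trait that couples loss-of-function
    mutations of the other two). Within-group birth-death-mutation dynamics
    are simulated exactly with Gillespie's Direct method and averaged over
    replicates; the resulting group-type developmental profiles drive an
    age-structured partial differential equation for the group population,
    advanced with a conservative finite-volume scheme using a superbee flux
    limiter. Includes drivers for within-group invasion experiments,
    steady-state parameter sweeps, and long-run evolutionary dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
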