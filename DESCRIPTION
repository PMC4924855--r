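Package: cravingdyn
Title: Dynamics of Craving and Self-Control in Addiction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates addiction as a two-variable stochastic difference-equation
    system in which weekly craving and the effect of self-control interact under
    an external control parameter and Poisson-distributed cue events. Provides
    the deterministic one-week map, closed-form equilibrium and stability
    analysis with a fold-bifurcation sweep over the external parameter, scenario
    simulations (addiction onset under lifestyle change, stationary relapse
    dynamics, therapeutic intervention), and a Monte Carlo harness estimating
    intervention success rates with Wilson confidence intervals. Includes a
    small command-line interface for reproducible, seeded runs with CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
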