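Package: warburgnfl
Title: Negative-Feedback-Loop Kinetic Model of the Warburg Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-variable kinetic model coupling cell
    proliferation to cytoplasmic NADH through a negative feedback loop,
    the mechanism proposed to underlie aerobic glycolysis (the Warburg
    effect). Provides the coupled ordinary differential equations and
    their closed-form steady states, the dimensionless IPPI number
    (inverse of potential-to-proliferation-increase) that classifies
    quiescent versus proliferative regimes, the NADH/NAD+ redox-ratio
    mapping and relative-proliferation curves, steady-state NADH flux
    decomposition, parameter sweeps (including a hypoxia scenario),
    a synthetic noisy-trajectory generator, and least-squares recovery
    of the six rate constants from trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
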