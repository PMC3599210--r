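Package: tkburden
Title: One-Compartment Toxicokinetics and Dietary Body-Burden Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for higher-tier mammalian risk assessment of pesticides
    from ADME (absorption, distribution, metabolism, excretion) study data.
    Fits one-compartment first-order toxicokinetic models to blood
    concentration-time profiles by weighted nonlinear least squares
    (Levenberg-Marquardt), with asymptotic confidence intervals and AIC
    model comparison against a two-compartment alternative; estimates
    relative oral bioavailability from dose-normalised AUC ratios; and
    predicts internal body burden under arbitrary feeding scenarios with a
    discrete-time gut/body two-pool simulator, including the bolus versus
    dietary exposure comparison. A synthetic-study generator emulates the
    rat ADME design (3 males + 3 females per group, nine sampling times,
    proportional measurement noise) so every stage of the pipeline is
    testable without access to the original in-life data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
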