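Package: hepatokin
Title: Whole-Body Compartmental Kinetics of Hepatobiliary MRI Contrast Agents
Version: 0.1.0
Authors@R:
    person("hepatokin", "developers", email = "hepatokin@example.org",
           role = c("aut", "cre"))
Description: Physiologically based whole-body compartmental modelling of the
    hepatocyte-specific MRI contrast agent gadoxetate (Gd-EOB-DTPA). Provides
    a family of linear and Michaelis-Menten kinetic model variants for plasma,
    extracellular extravascular space, hepatocyte and splenic compartments
    with biliary and renal elimination sinks; an MRI relaxivity-change signal
    model for region-of-interest data; chi-square ensemble parameter
    estimation by simulated annealing; profile-likelihood identifiability
    analysis; core-prediction uncertainty envelopes; volume sensitivity and
    simulated loss-of-liver-function experiments; and a synthetic-data
    generator emulating clinical bolus DCE-MRI and high-dose infusion
    blood-sampling designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
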