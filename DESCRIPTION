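Package: pbpkddi
Title: Whole-Body Parent-Metabolite PBPK Modeling of Carbamazepine with
    Enzyme Induction and Drug-Drug Interaction Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK)
    simulator for the anticonvulsant carbamazepine and its active
    metabolite carbamazepine-10,11-epoxide. Implements perfusion-limited
    distribution with Rodgers-Rowland tissue partitioning, oral absorption
    with Weibull dissolution and fed/fasted gastric emptying,
    Michaelis-Menten and first-order enzymatic clearances, dynamic enzyme
    turnover with Emax (auto-)induction, mechanism-based and competitive
    inhibition, and glomerular filtration with a GFR fraction. Provides
    study-protocol simulation, drug-drug interaction co-simulation,
    non-compartmental exposure metrics (AUClast, Cmax, DDI ratios),
    model-performance statistics (MRD, GMFE, two-fold fraction, Guest
    prediction-success limits), Levenberg-Marquardt parameter estimation
    with Monte-Carlo multistart, and a synthetic clinical-study generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
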