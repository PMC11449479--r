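Package: lppkin
Title: Isotopologue Mass Calculation and Tethering Kinetics of the Braun
    Lipoprotein on Peptidoglycan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of heavy-isotope (13C/15N) pulse-chase labeling of the
    Escherichia coli Tri->KR muropeptide, the diagnostic fragment of
    peptidoglycan-tethered Braun lipoprotein (Lpp). Provides an elemental
    composition and monoisotopic mass engine for branched, reduced,
    moiety-wise labeled muropeptides and their MS2 fragment ladder; peak
    assignment and isotopologue relative-abundance quantification; a
    deterministic ODE model of growth dilution, Lpp tethering and YafK
    hydrolysis with a stochastic simulation oracle; least-squares parameter
    estimation with replicate bootstrap; and a seeded synthetic-data
    generator emulating the labeling experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
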