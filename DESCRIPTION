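Package: revpot
Title: Coupling Stoichiometry of Electrogenic Transporters from Reversal Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the ion:substrate coupling stoichiometry of
    electrogenic secondary active transporters from reversal-potential flux
    experiments in proteoliposomes. Provides an equilibrium-thermodynamics
    engine for arbitrary ion-coupled transport cycles (reversal potentials,
    per-cycle free energies, Nernst potentials, equilibrium substrate ratios),
    forward and inverse design of valinomycin/K+ voltage-clamp experiments,
    a synthetic radiotracer flux-assay generator with thermodynamically
    consistent kinetics and scintillation counting noise, and an inference
    stage that classifies flux direction per clamped voltage, brackets the
    reversal potential, and assigns or excludes candidate stoichiometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
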