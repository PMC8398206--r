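Package: dftbench
Title: Benchmarking DFT Functional/Basis-Set Combinations for Antioxidant Reactivity Indices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ranking density-functional-theory (DFT) levels of theory
    for polyphenol antioxidant studies. From per-species enthalpies and
    frontier-orbital energies of a phenolic antioxidant it computes the
    classical reactivity indices (bond dissociation enthalpy, adiabatic and
    vertical ionization potential and electron affinity via Janak's theorem,
    proton affinity), signed errors and mean-absolute-error summaries against
    reference values, ordinary-least-squares models of those errors on
    Hartree-Fock-exchange and basis-set features with significance-based
    backward reduction, CPU-time normalization for the SCF and two-electron
    integral program stages, and a weighted threshold scoring function that
    ranks every functional/basis-set combination. A seeded synthetic-data
    generator reproduces the full benchmark grid so the entire pipeline can be
    exercised without any quantum-chemistry computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
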