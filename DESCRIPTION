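Package: fibrilkin
Title: Nucleation and Autocatalytic Growth Kinetics of Self-Assembling
    Polypeptide Nanofibrils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and fits the assembly kinetics of biomimetic
    polypeptide (BMPP) nanofibrils with a three-reaction scheme:
    nucleation (A -> B), autocatalytic growth by monomer addition
    (A + B -> 2B), and fibril end-joining (B + B -> 2B).  Provides
    deterministic integration of the scheme, its Finke-Watzky
    closed-form limit, an exact event-driven stochastic simulator with
    per-fibril lengths for AFM-comparable geometry statistics, a
    turbidity (OD340) observation model with Savitzky-Golay derivative
    heuristics and multi-start nonlinear least-squares extraction of
    the rate constants, a two-state coil-to-helix circular-dichroism
    decomposition, the 2^-ddCt relative-expression readout, and seeded
    synthetic-data generators for every input the pipeline consumes.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
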