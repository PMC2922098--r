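Package: floralfate
Title: Continuous-Time Modelling of Floral Organ Fate Determination in Arabidopsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ordinary differential equation model of the six-gene MADS-box
    regulatory network (AP1, AP3, PI, AG, SHP, SEP) that determines floral
    organ identity in the four whorls of the Arabidopsis flower. Protein
    dimerization is modelled explicitly with mass-action kinetics and reduced
    by a quasi-steady-state elimination to an implicit six-variable system
    solved through a state-dependent mass matrix. The package provides the
    full coupled monomer-dimer model, the reduced model, the transformation
    of meristem-averaged expression intensities into whorl-resolved protein
    concentrations, decoupling-based least-squares parameter identification,
    in-silico knockout, ectopic-expression and dimer-removal experiments with
    ABCDE organ-identity classification, and a seeded synthetic-data
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
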