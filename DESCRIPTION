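Package: helamp
Title: Design and Characterization of Perfectly Amphipathic Helical
    Antimicrobial Peptides
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the de novo design of perfectly amphipathic helical
    antimicrobial peptide isomer families (leucine/lysine undecapeptides with
    a single interface tryptophan) and for the quantitative apparatus used to
    characterize them: helical-wheel geometry and physicochemical descriptors
    (mean hydrophobicity, Eisenberg hydrophobic moment, polar angle, mass,
    charge), antimicrobial and hemolytic activity indices (geometric-mean MIC,
    minimal hemolytic concentration, pseudo-therapeutic index), circular
    dichroism ellipticity normalization and helicity estimation, tryptophan
    fluorescence emission maxima and alpha-proton secondary chemical shifts,
    and ordinary least-squares structure-activity regression.  Seeded
    synthetic-data generators emulate every input kind (CD spectra as
    helix/coil basis mixtures, skewed emission peaks, Hill-type hemolysis
    curves, two-fold-quantized MIC tables) so each stage is testable without
    external data.  A unified command-line entry point exposes all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
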