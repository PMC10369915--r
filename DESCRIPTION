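Package: sh2profiler
Title: Enrichment Scoring, Binding Models, and Coupling Energetics for
    SH2 Domain Phosphopeptide Specificity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative analysis of SH2 domain phosphopeptide specificity
    profiling by bacterial peptide display. Counts deep-sequencing reads
    against defined peptide libraries, computes frequency-ratio enrichment
    scores with replicate handling, calibrates hit cutoffs from
    tyrosine-free negative controls, and builds position-specific sequence
    logos and scanning-mutagenesis matrices. Also fits direct and
    competitive fluorescence-polarization binding titrations with exact
    ligand-depletion and ternary competitive equilibrium models, fits
    phosphopeptide-dependent phosphatase activation curves (EC50), and
    computes double-mutant-cycle coupling free energies. Includes a
    synthetic-data generator (multinomial selection screens and noisy
    titrations) so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
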