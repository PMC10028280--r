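Package: ClonoTrack
Title: Longitudinal B-Cell Receptor Repertoire and Ig Proteome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal analysis of immunoglobulin heavy-chain
    (IGH) repertoires from UMI-tagged amplicon sequencing. Implements
    quality filtering, UMI consensus building and duplicate collapsing,
    simplified V/J germline assignment with AIRR Rearrangement TSV
    import/export, clonal inference by CDR3 identity clustering,
    Hill-number diversity with bootstrap resampling, classification of
    clones by the exact set of sampled time points they span, overlap of
    serum Ig tryptic peptides with the BCR transcriptome, and the
    nonparametric statistical comparisons used in treatment-course
    repertoire studies. A synthetic-repertoire generator with power-law
    clone sizes, somatic hypermutation, subset barcoding and a
    memory-compartment depletion effect provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
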