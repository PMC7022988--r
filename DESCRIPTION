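Package: repsatk
Title: REPSA Selection Analysis, Motif Discovery, Genome Scanning, Binding
    Kinetics, and Regulon Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring a transcription factor's DNA-binding
    consensus and candidate regulon from in-vitro selection (REPSA/SELEX-like)
    sequencing data. Covers randomized-cassette extraction from selection-round
    FASTQ reads, expectation-maximization motif discovery with an optional
    palindromic constraint, position-weight-matrix genome scanning with exact
    match p-values and Benjamini-Hochberg false discovery rates, global 1:1
    Langmuir fitting of label-free (biolayer interferometry) sensorgrams,
    equilibrium binding estimation from gel-shift titrations, empirical-Bayes
    moderated-t differential expression, and an end-to-end pipeline that joins
    binding sites, affinities, and expression changes into a candidate-regulon
    report. Includes synthetic-data generators with known ground truth for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    minpack.lm,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
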