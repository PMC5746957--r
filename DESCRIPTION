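Package: clipHMM
Title: Crosslink Site Detection from Single-Nucleotide CLIP-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls individual protein-RNA crosslink sites from iCLIP/eCLIP
    read-start data using a four-state (non-)homogeneous hidden Markov model.
    Read starts mark reverse-transcription truncation events; the model couples
    a left-truncated gamma distribution on kernel-smoothed pulled-down fragment
    densities (enrichment) with a zero-truncated binomial on per-position read
    start counts (crosslinking), trained by Baum-Welch with numerically
    optimised M-steps. Optional covariates correct for non-specific background
    (input-control fragment density through a gamma GLM with log link) and for
    crosslinking sequence bias (per-motif logistic regressions on CL-motif
    match scores). Includes an iCLIP/eCLIP read simulator with ground-truth
    crosslink annotations and evaluation statistics (motif-anchored precision,
    splice-site positioning, simulation precision/recall, bias-corrected
    replicate agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    fitdistrplus,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
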