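Package: flankPref
Title: Flanking-Sequence Preference Analysis of De Novo DNA
    Methyltransferases from Hairpin Bisulfite Deep Enzymology
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deep-enzymology profiling of the CpG-flanking
    sequence preferences of de novo DNA methyltransferases (DNMT3A and
    DNMT3B). Simulates pools of double-stranded substrates in which the
    target cytosine is embedded in randomized flanks, models enzymatic
    methylation under a known preference model, and emits hairpin-ligated
    bisulfite-converted sequencing reads. Reconstructs the original duplex
    sequence and per-strand methylation state from hairpin reads, tabulates
    methylation levels per k-mer flanking context (NNCGNN, NNNCGNNN),
    computes positional base-enrichment profiles, position frequency
    matrices of preferred sites, normalized enzyme-versus-enzyme preference
    ratios and rankings, similarity-to-motif binning, and strand-resolved
    CpG-site rank analysis of repeat sequences. Also provides the bespoke
    post-alignment summaries used for cellular methylomes: read-level
    bisulfite non-conversion filtering, exact binomial methylation calling,
    spike-in conversion QC, and depth-filtered genomic context aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Sequencing, Software
RoxygenNote: 7.3.3
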