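Package: divmig
Title: Divergence and Migration Inference from Blockwise Site Frequency
    Spectra of Diploid Transcriptome Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood inference of two-population divergence
    histories (strict divergence and isolation-with-migration models, with
    or without a post-split change in effective size) from pairs of
    unphased diploid genomes. Implements the blockwise site frequency
    spectrum (bSFS) likelihood for blocks of fourfold degenerate sites via
    exact structured-coalescent calculations, a matching Monte-Carlo
    simulator, robust orthogroup filtering for de novo transcriptome
    assemblies, construction of site-class blocks from coding-sequence
    alignments and VCF genotypes, parametric bootstrap of site-frequency
    fits, model comparison, and conversion of scaled estimates to absolute
    quantities.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
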