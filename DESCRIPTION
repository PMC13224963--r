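Package: straindecon
Title: Strain Genotype Reconstruction from Short-Read Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs up to three bacterial strain genotypes and their
    relative frequencies from paired-end short-read metagenomic data mapped
    against an annotated reference genome. Reads are mapped to a database of
    flank-extended genes, allele variants are called under base-quality,
    frequency and depth filters, co-observed alleles are linked into linkage
    groups spanning genes, and a stochastic search over the strain-frequency
    simplex fits a hexamodal allele-frequency peak model. Phased genotypes
    are emitted with ambiguous positions masked as N and near-identical
    genotypes collapsed by average nucleotide identity. Ships with a
    paired-end strain-mixture read simulator and evaluation metrics for
    strain count, frequency and genotype accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
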