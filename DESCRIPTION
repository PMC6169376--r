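Package: svconcord
Title: Structural-Variant Calling and Cross-Line Concordance from Genome
    Assemblies and Optical Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls structural variants (>50 bp) between genome assemblies and a
    reference from unique-anchor whole-genome alignments, classifies them into
    the six alignment-gap classes (insertion, deletion, tandem and repeat
    expansion/contraction) plus inversions, detects large SVs independently
    from nick-site label maps (optical maps) and cross-validates the two call
    sets, builds a cross-line SV coincidence matrix with base-pair tolerance
    matching, derives a relationship tree with bootstrap (BP) and approximately
    unbiased (AU) clade supports via multiscale bootstrap, quantifies exonic
    impact, and estimates an SV rate per MY per Mb. Includes a synthetic-genome
    simulator that plants SVs of all classes along a known line tree with
    matched exon annotations and noisy label maps, providing ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
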