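Package: srnaloci
Title: Uniform Annotation of Plant Small RNA Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates the three major classes of plant small RNA producing
    loci from a genome and collapsed small RNA sequencing libraries: MIRNA
    hairpin loci under stringent duplex and abundance criteria, 21- and 24-nt
    phased siRNA (PHAS) loci by an exact hypergeometric phasing p-value and
    phasing score with a repetitiveness filter for the 24-nt class,
    heterochromatic siRNA loci from 24-nt dominated repeat-associated read
    clusters, and archetypal TAS3 genes by dual miR390 target sites with
    tasiARF reporting. Includes a truth-tracked synthetic data generator so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
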