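Package: mirforge
Title: Discovery and Annotation of Plant MicroRNAs from Small RNA
    Sequencing and Genome-Survey Scaffolds
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a homology-plus-structure
    microRNA discovery workflow for plants without a reference genome:
    small RNA read cleaning and collapsing, k-mer based genome-size
    estimation, conserved miRNA identification by mismatch-tolerant
    homology to known mature miRNAs, novel miRNA prediction from
    hairpin secondary structures under twelve structural criteria with
    the minimal folding free energy index (MFEI), complementarity-based
    target prediction with in-silico cleavage-site mapping, microarray
    and stem-loop qRT-PCR expression mathematics, and hypergeometric
    pathway enrichment. Ships a fully synthetic data generator with
    known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
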