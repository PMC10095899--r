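Package: crispgeno
Title: Amplicon Sequencing Genotyping of CRISPR-Edited Individuals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for high-throughput genotyping of CRISPR/Cas9-edited
    individuals by two-step barcoded amplicon sequencing: combinatorial
    frameshift-barcode design and validation, PAM-site scanning restricted to
    haplotype-invariant sequence, two-stage read demultiplexing (plate index,
    then exact-match nine-base frameshift prefixes), a banded glocal aligner
    with pileup-based small-variant calling and zygosity classification, VCF
    output, library pooling-normalization arithmetic, a sequencing-run
    capacity model, and a paired-end read simulator for end-to-end validation
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, Biostrings, jsonlite, stats, utils, tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), vcfR, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
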