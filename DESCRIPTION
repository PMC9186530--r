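Package: graphasm
Title: Homopolymer-Compressed String-Graph Assembly of Long Reads at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for telomere-to-telomere style assembly of
    haploid genomes from simulated long reads. Implements homopolymer
    compression of accurate (HiFi-like) reads, all-vs-all correction with
    masking of simple-sequence-repeat differences, exact-overlap bidirected
    string-graph construction and simplification, multiplicity-guided walk
    enumeration with ultra-long (ONT-like) read arbitration, run-length
    consensus, a sparse de Bruijn "morph" assembler for rDNA-like tandem
    arrays, and a validation suite (coverage uniformity, unique k-mer
    markers, marker-assisted read assignment, allele ratios, windowed
    identity, NG50 and issue catalogs). A synthetic genome and read
    simulator provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
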