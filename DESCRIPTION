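Package: tudscan
Title: Alignment-Free Genome Comparison by Oligonucleotide Usage Deviation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes tetranucleotide (and general k-mer) usage deviation
    vectors for nucleotide sequences: observed word counts on a genome
    extended by its reverse complement, divided by expected counts under a
    zero-order Markov (mononucleotide composition) model. Usage deviation
    vectors support alignment-free comparison of genome collections through
    Euclidean distance matrices, neighbor-joining and average-linkage trees,
    and principal components analysis, as well as within-genome sliding-window
    scans that highlight compositionally anomalous regions such as putative
    horizontal gene transfer, and per-word usage tracks along a genome. A
    synthetic-community generator produces Markov-model genomes with
    cluster-structured composition biases, planted foreign segments and
    tandem-repeat blocks, with full ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
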