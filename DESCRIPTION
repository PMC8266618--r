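Package: aakmer
Title: Taxonomic Classification of Reads with Amino-Acid-Like Encoded k-mers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Memory-budgeted taxonomic identification and profiling of
    sequencing reads against a sorted index of amino-acid-like encoded
    k-mers. Nucleotide sequences are translated in up to six reading
    frames through a codon table, packed into order-preserving fixed-width
    words (five bits per letter), and stored as a sorted (k-mer, taxon)
    index with a depth-six prefix trie for range lookup. Reads are matched
    over a range of k simultaneously and scored with a quadratic
    length-weighted k-mer score and a frequency-normalized relative score;
    per-k taxonomic profiles report unique, non-unique and overall
    relative frequencies. Includes lossless index halving, per-taxon lossy
    shrinking, a seeded read simulator with per-base substitution
    mutations, and per-read sensitivity/precision/F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
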