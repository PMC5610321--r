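Package: mevtree
Title: Alignment-Free Phylogenies from Multiple Encoding Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Alignment-free comparison of DNA sequences via an 18-dimensional
    "multiple encoding vector": each sequence is recoded under three binary
    alphabets (purine/pyrimidine R/Y, amino/keto M/K, strong/weak H-bond S/W)
    and summarised, per letter, by its count, mean position and scaled second
    moment of positions. Sequences are compared by Euclidean distance between
    vectors and clustered into rooted ultrametric trees with a native UPGMA
    implementation. A k-mer feature-frequency-profile (FFP) baseline with
    Jensen-Shannon divergence, the floor(log4 n) k-selection rule, a
    clade-structured sequence simulator, FASTA/PHYLIP/Newick input-output and
    a command-line driver are included for head-to-head evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
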