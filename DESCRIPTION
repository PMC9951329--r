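Package: popdiv
Title: Two-Population Sequence Diversity and Divergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Per-locus diversity and divergence statistics for labeled
    multi-sequence alignments of two populations: segregating sites,
    nucleotide diversity, Watterson's theta, Tajima's D, Dxy, Nei's net
    divergence dA, Hudson's FST and nearest-neighbor statistic Snn, and
    Nei-Gojobori codon-level Ka/Ks with Jukes-Cantor correction.
    Significance is assessed by seeded population-label permutation tests,
    distributions are contrasted with the two-sample Kolmogorov-Smirnov
    statistic, and outlier loci are selected by a joint upper-quantile rule
    on dA and Snn. A two-deme split-model coalescent simulator with
    infinite-sites mutation generates labeled alignments (including the
    panmictic null) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
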