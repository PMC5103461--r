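Package: yeastcomp
Title: Comparative Genomics of Closely Related Yeast Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying genome-level divergence between closely
    related yeast strains. Implements sliding-window nucleotide divergence over
    whole-genome alignments (1-kb windows with a minimum-called-site filter and
    flank smoothing), an alignment-free Kr distance built on shustrings
    (shortest substrings absent from the partner genome) with Monte-Carlo
    calibration and Jukes-Cantor correction, targeted seed-and-extend assembly
    of high-copy replicons gated by per-column information content,
    coverage-ratio copy-number estimation, gene and intron architecture
    statistics (N50, GC, intron-less gene fraction, introns per gene), and
    reciprocal best-hit orthology with a sequential orphan-gene filter chain.
    A seeded synthetic-data module generates every input the pipeline consumes
    so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
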