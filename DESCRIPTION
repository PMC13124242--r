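Package: karyomer
Title: Alignment-Free Computational Karyograms, Assembly Completeness, and
    Short-Read Phasing from k-mer Feature Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds exact k-mer feature databases from an annotated reference
    genome (telomere, centromere, and chromosome-specific arm features),
    annotates assembly contigs and scaffolds against them without alignment,
    and renders deterministic computational karyograms. Classifies every
    contig into five structural-completeness categories (complete chromosome,
    complete arm, partial arm, centromere, marker), computes expected-genome-
    size contiguity statistics (NGx/LGx curves, NG50, LG50, auN), and phases
    paired-end short reads against a diploid assembly by summed alignment
    score or by mapping quality, with exponential fits and two-sample
    Kolmogorov-Smirnov diagnostics of the concordant versus discordant score
    distributions. Includes a deterministic synthetic genome, assembly, and
    read-pair simulator so every component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    grDevices,
    utils,
    methods,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
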