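Package: treprofiler
Title: Retrotransposon Integration-Site Profiling at RNA Polymerase III Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling tRNA gene-targeted retrotransposon integration
    from paired-end amplicon sequencing (LAM-PCR libraries). Builds catalogs of
    RNA polymerase III integration targets (tRNA genes, 5S genes, and A/B-box
    promoter loci found by degenerate motif scanning), merges read pairs into
    pseudoreads, trims element and primer parts, maps junction fragments with a
    seed-and-extend local aligner under second-best-hit and query-coverage
    acceptance rules, calls deduplicated integration events with distances to
    the target +1 nucleotide, 5' truncations and non-templated extra
    nucleotides, and summarises distance distributions, target occupancy and
    hot-spot bias. Includes a synthetic-data generator that plants integrations
    with a machine-readable truth set so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
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
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
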