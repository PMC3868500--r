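Package: smallrnadx
Title: Two-Library Small RNA Sequencing Analysis with the Audic-Claverie Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidy toolkit for comparing two pooled small-RNA sequencing
    libraries (a case library versus a control library), as used in
    profiling studies of membranous nephropathy. Covers read cleaning
    (quality filtering, 3' adaptor trimming, 5' contaminant removal, tag
    collapsing), exact-match genome mapping with unique/total mapping
    summaries, known-miRNA counting against a mature reference,
    per-position base composition, per-million normalization with an
    absence floor, log2 fold change with the Audic-Claverie count
    statistic, seed-region (positions 2-8) base-edit detection and
    case/control edit-ratio classification, 2^-ddCt qPCR concordance
    checks, pairwise fold-change matrices with hierarchical clustering,
    and a seeded synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
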