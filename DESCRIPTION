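Package: enhancerdyn
Title: Enhancer Chromatin Dynamics from Coverage Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of enhancer-centric chromatin dynamics from normalized
    sequencing coverage tracks and peak/gene annotations: geometric-mean
    anchored metaplots, metagene profiles with scaled gene bodies and fixed
    1 kb flanks, androgen-regulated gene sets from differential-expression
    tables, nearest AR-positive enhancer assignment, rank-ordering
    super-enhancer calling with a slope-one tangent cutoff, and paired-sample
    accessibility tests with Bonferroni-style thresholds. Includes a
    seed-driven synthetic data generator that plants mark-, timepoint- and
    genotype-specific enrichment amplitudes, regulated genes and a clustered
    super-enhancer so every stage is testable without sequencing data, and a
    configuration-driven pipeline runner that ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
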