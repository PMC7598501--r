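Package: centroscope
Title: Centromere Profiling from Low-Pass Reads, ChIP Enrichment and
    Fluorescence Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for profiling repeat-based centromeres
    in species whose (peri)centromeric satellite arrays are missing from
    the genome assembly.  Unassembled low-pass whole-genome reads are
    grouped into repeat clusters by graph-based similarity clustering,
    ChIP and input reads are mapped onto the clusters to score CenH3
    enrichment with dual candidate-selection criteria, satellite clusters
    are decomposed into subfamily proportions, transcript hit counts are
    normalized as counts per million, and centromere extent and
    two-channel signal co-localization are quantified from fluorescence
    line profiles.  A synthetic repeatome generator emulating a
    satellite-rich beetle genome provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
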