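Package: circlekit
Title: Detection, Simulation and Profiling of Extrachromosomal Circular DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for extrachromosomal circular DNA (eccDNA) analysis
    from Circle-Seq short reads and rolling-circle-amplified long reads:
    a junction caller based on quality-aware soft-clip realignment and
    outward-facing discordant pairs with a six-part filter suite, a
    benchmark simulator (synthetic genomes, planted circles, junction
    reads, multi-pass concatemer reads, clustered SNVs), per-gene eccDNA
    abundance normalization and differential-abundance statistics,
    kataegis and kyklonas detection against ecDNA intervals with
    96-context mutation spectra, genomic-element and repeat profiling
    with shuffled in-silico baselines, and reconstruction of (possibly
    chimeric) circle fragment compositions from PAF alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
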