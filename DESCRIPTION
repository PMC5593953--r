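Package: tgloc
Title: Localization of Complex Transgene Insertions from Paired-End
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to localize a complex, multi-part transgene insertion
    from paired-end whole-genome sequencing reads mapped against a
    composite genome-plus-vector reference. Provides a synthetic-data
    module that builds wild-type and transgenic haplotypes carrying a
    two-sub-site insertion (a short vector fragment plus a multi-copy
    concatemer) with associated genomic deletions, a paired-end read
    simulator with machine-readable truth sets, a minimal seed-and-extend
    read mapper with SAM input/output, a structural-variant caller that
    clusters chimeric-pair and split-read evidence into breakpoint calls
    and estimates transgene copy number from relative depth, windowed
    read-depth deletion calling and locus copy-number genotyping, and
    chi-square segregation and penetrance statistics for breeding-colony
    genotype-phenotype count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
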