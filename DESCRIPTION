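Package: minorcall
Title: Detection of Low-Level Mutations from Deep Multi-Sample Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes low-level mutations (minor-allele frequencies well
    below 50%, e.g. mitochondrial heteroplasmies, somatic variants, variants in
    pooled samples) from sequencing errors in deep multi-sample resequencing of
    a small shared target. Reads are stratified into strand by read-position
    bins, a position- and bin-specific sequencing-error profile is estimated
    from all other samples sharing the consensus nucleotide, and the deviation
    of the observed minor-allele count from the error expectation is scored per
    strand with three alternative tests (Poisson tail, one-sided Fisher exact,
    empirical rank) combined into a Phred-like quality score. Includes screens
    for strand-specific error hot spots, sample cross-contamination and
    chimeric reads, and a wgsim-style read simulator with truth tables for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    Biostrings,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
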