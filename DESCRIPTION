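Package: tiger
Title: Calling Non-Reference Germline L1-Mediated 3' Transductions from
    Paired-End Sequencing Data
Version: 0.1.0
Authors@R:
    person("TIGER", "Maintainers", email = "tiger@example.org", role = c("aut", "cre"))
Description: Detects non-reference germline LINE-1 (L1) mediated 3'
    transductions in paired-end short-read whole-genome sequencing data.
    Starting from mobile element insertion (MEI) calls produced by any
    upstream caller, candidate regions are scanned for translocation-like
    (TL) and single-anchored (SA) discordant read pairs, mates are
    realigned to the reference with a mappability-aware seed-and-extend
    aligner, and realigned mates are clustered into transduction source
    loci. Calls are annotated with target site duplication and polyA
    hallmarks, filtered against segmental duplications and reference L1
    annotation, and classified by donor context. The package also provides
    transduction-rate statistics (t-based confidence intervals, Wald
    species comparisons, validation-based false discovery rates), L1
    subfamily assignment with Fisher-exact enrichment testing, a long-read
    verification module that decomposes inserted sequences into truncated
    L1, transduced sequence and polyA segments, and a full synthetic-data
    simulator (genome, implanted events, paired-end reads) for end-to-end
    benchmarking without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    Rsamtools,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
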