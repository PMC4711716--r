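Package: blockalign
Title: Seed-and-Extend Short-Read Alignment with On-Demand Block Scheduling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale short-read aligner and parallel work-distribution
    framework. Reads are mapped to a reference genome with a seed-and-extend
    cascade (maximal-exact-match seeds, exact-match k-mer rescue, banded
    affine-gap local extension, semi-global rescue and paired-end mate
    rescue), and the alignment workload is distributed over worker processes
    in blocks claimed on demand from a lock-protected shared counter, with
    per-worker intermediate SAM files merged by a dedicated gatherer
    process. A static equal-share distribution and a makespan simulator are
    included for comparing the two scheduling policies, and a synthetic
    genome/read generator with planted truth supports end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
OS_type: unix
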