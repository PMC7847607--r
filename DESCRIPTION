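Package: phasloc
Title: Discovery and Degradome Validation of Phased siRNA (PHAS) Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects 21- and 24-nt phased small interfering RNA (phasiRNA)
    precursor loci in transcript sequences from collapsed small-RNA
    libraries, scores phasing with a five-register sliding-window
    statistic, identifies and validates sRNA triggers and phasiRNA
    targets against degradome (PARE) 5'-tag profiles, calls DCL
    dependence from wild-type versus dcl-mutant libraries, and analyses
    24-nt phasiRNA-directed promoter methylation (RdDM) from bisulfite
    and RNA-seq read libraries. Includes a seeded synthetic-data
    generator that plants ground-truth loci, triggers, targets and
    methylation patterns for every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
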