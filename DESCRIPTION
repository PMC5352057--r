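Package: chordomics
Title: Genomic and Transcriptomic Profiling of Skull Base Chordoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize skull base chordoma cohorts from
    paired-end RNA alignments and whole-exome data: coverage-based gene
    fusion detection from discordant read pairs with per-nucleotide
    breakpoint inference and reading-frame calls, aCGH-like exome copy
    number profiles with pseudo-normal references and binary segmentation,
    somatic mutation burden and 96-trinucleotide-context spectra with
    NpCpG C>T prominence scoring, RPKM expression quantification and
    rank-based group comparisons, and Pearson chi-squared genotype
    association for the brachyury (T gene) rs2305089 risk variant.
    Includes a deterministic synthetic-cohort generator so every stage is
    testable without access to patient sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
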