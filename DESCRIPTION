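Package: viromine
Title: Mining Metagenome Reads for Giant Virus and Virophage Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A staged pipeline for detecting reads related to large and
    giant DNA viruses (Megavirales) and virophages in metagenomes. Raw
    FASTA/FASTQ read sets are cleaned (deduplication, length and ambiguity
    filters), searched against a labelled query sequence set with a
    built-in seed-and-extend local aligner (nucleotide or six-frame
    translated mode, Karlin-Altschul E-value statistics) or with
    externally computed tabular hit files, and each candidate read is
    confirmed by a reciprocal best-hit test against a reference database.
    The package also provides a synthetic-metagenome simulator with truth
    labels, per-taxon tallies, run summaries, and classifier-agreement
    statistics (Cohen's kappa, Yates-corrected chi-square) for comparing
    annotation tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
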