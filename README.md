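# viromine

Mining metagenome read sets for sequences related to large and giant DNA
viruses (the proposed order *Megavirales*) and virophages.

Environmental and human metagenomes contain a large fraction of
unannotated "dark matter", and giant-virus reads are routinely missed by
generic annotation services. `viromine` implements a three-step detection
pipeline for anyone who wants to screen reads against a *customized*
query sequence set (for example, a curated collection of giant-virus
genomes or proteins) with a stringent confirmation step:

1. **Clean** — convert FASTA/FASTQ input to FASTA and remove duplicated
   reads, reads shorter than 40 nt, and reads with more than 20%
   ambiguous positions (all thresholds adjustable).
2. **Search** — align the cleaned reads against the query set, either
   with the built-in seed-and-extend local aligner (BLASTn-like
   nucleotide mode, or tBLASTn-like six-frame translated mode for
   protein queries) or by ingesting an external aligner's 12-column
   tabular output. Hits are thresholded on a Karlin–Altschul E-value,
   E = K·m·n·e^(−λS), default cutoff 1e-5, with λ and K computed exactly
   from the scoring scheme.
3. **Confirm** — a reciprocal best-hit (RBH) test: each candidate read is
   re-searched against a reference database containing the query set,
   and is confirmed **positive** only if its best hit (minimum E-value,
   ties by bit score, then subject id) belongs to a target taxon.

The package also ships a synthetic-metagenome simulator with per-read
truth labels, so the whole pipeline is testable without downloading any
data, and the agreement statistics used to compare annotation tools on
the same read universe (Cohen's kappa and the Yates-corrected chi-square
on a 2×2 contingency table).

## Worked example

Simulate a metagenome with 200 reads planted from three 10 kb "virus"
sources among 10,000 random background reads, then run the pipeline:

```r
library(viromine)

src <- random_sources(n = 3, length = 10000, seed = 61, prefix = "virus")
sim <- generate_metagenome(simulation_params(
  n_background = 10000, n_planted = 200, read_length = 100,
  sources = src, substitution_rate = 0, ambiguity_rate = 0,
  duplication_fraction = 0, seed = 17))

dir.create("demo")
write_fasta(sim$records, "demo/reads.fasta")
write_fasta(src, "demo/query.fasta")
write.table(data.frame(src$id, "Mimiviridae", 1), "demo/taxa.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

cfg <- pipeline_config(reads = "demo/reads.fasta",
                       query = "demo/query.fasta",
                       taxa = "demo/taxa.tsv", out_dir = "demo/out")
run_pipeline(cfg)
#> [clean] 10200 of 10200 reads retained
#> [search2] 201 hits for 201 reads
#> [search3] 201 reference hits for 201 candidates
#> [classify] 201 positive of 201 candidates
```

All 200 planted reads are recovered (one additional background read
carries a 23/24-nt chance identity to a source, significant at this
search-space size). The output directory contains the pipeline's four
result files — `step2_hits.tsv` (raw first-pass hit table),
`positive_hits.tsv` (reference hits of confirmed reads),
`positives.fasta` (the confirmed reads), `summary.txt`/`summary.json`
(run summary) — plus `classifications.tsv` with each candidate's
verdict (`positive`, `negative`, `ambiguous` or `unresolved`) and its
best-hit evidence.

Comparing two annotation tools over one read universe:

```r
res <- agreement_result(a = 1031, b = 79, c = 0, d = 1636697 - 1110,
                        raw_count_b = 26506)
res
#> Tool agreement
#>   both positive: 1031 | A only: 79 | B only: 0 | both negative: 1635587
#>   Cohen's kappa: 0.963
#>   corrected chi-square: 2.844 (p = 0.092)
#>   extra reads by A: 79 (8% more)
#>   raw/confirmed fold ratio: 24
```

A thin command-line wrapper with subcommands (`convert`, `clean`,
`search`, `classify`, `simulate`, `compare`, `run`) is installed at
`system.file("cli", "viromine.R", package = "viromine")`.

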