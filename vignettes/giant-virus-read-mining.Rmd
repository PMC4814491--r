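---
title: "Detecting giant-virus and virophage reads in metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting giant-virus and virophage reads in metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromine)
```

## The problem and the method

Metagenome read sets routinely contain sequences from nucleocytoplasmic
large DNA viruses (mimiviruses, phycodnaviruses, pandoraviruses,
pithoviruses, faustoviruses — the proposed order *Megavirales*) and from
their virophage parasites, but generic annotation pipelines under-report
them. `viromine` implements the targeted strategy used for this class of
question: screen all reads against a *curated query set* of giant-virus
sequences, then demand that each candidate survive a reciprocal best-hit
(RBH) confirmation against a reference database before it is counted.

The pipeline has three stages, communicating through files so that any
stage can be re-run independently or replaced by an external tool:

1. **Cleaning.** Reads are converted to FASTA and filtered: exact
   duplicate sequences (keep-first policy by default), reads shorter
   than `min_length` (default 40 nt, strict), and reads whose fraction
   of ambiguous positions exceeds `max_ambiguity_frac` (default 0.20,
   strict; every non-ACGT letter counts, restrictable to `N`). Each
   removed read is attributed to the *first* rule it violates —
   duplicate, then length, then ambiguity — so the report counts are
   well defined and sum to the input count.

2. **First-pass search.** Cleaned reads are searched against the query
   set, in nucleotide mode when the query set is DNA (at least 90%
   ACGTN residues) or in six-frame translated mode when it is protein.
   Reads with any hit at E ≤ `evalue_cutoff` (default 1e-5; the
   published re-analysis of an ocean-virome dataset used 1e-3, so both
   steps' cutoffs are independently configurable) become candidates.

3. **RBH confirmation.** Candidates are searched against a reference
   database that must contain the query set (the pipeline verifies this
   through the taxon map and refuses to run otherwise, unless
   explicitly allowed). A candidate is `positive` if its best hit —
   minimum E-value, ties broken by maximum bit score, then smallest
   subject id, a total and order-independent rule — belongs to a target
   taxon; `negative` if a non-target sequence wins; `ambiguous` if
   target and non-target subjects tie exactly on (E-value, bit score),
   a specificity-first choice; `unresolved` only when a
   query-set-lacking reference yields no hits at all.

## The built-in searcher and its statistics

So that the pipeline is fully testable standalone, the package includes
a desk-scale seed-and-extend searcher with a proper alignment core,
rather than shelling out to an external aligner (external 12-column
tabular hit files are ingested through the same contract and are the
intended scale path).

* **Seeding.** Exact k-mer matches (default k = 11 nucleotide, 3 amino
  acid) between read and database, on both strands in nucleotide mode;
  in translated mode the six reading frames are split at stop codons
  and each segment is searched separately, mirroring how
  protein-vs-translated searches avoid alignments through stops.
* **Extension.** Each seeded read/subject pair is extended by an
  optimal Gotoh (affine-gap Smith–Waterman) alignment, computed in C++,
  restricted to a window spanning the pair's seed diagonals plus one
  read length plus the `x_drop` allowance (default 20) — wide enough
  that any alignment passing through a seed is recovered in full. A
  reported alignment must *contain* a seed; if the window optimum is
  unanchored (a chance alignment elsewhere in the window), each seed is
  re-extended on a narrow band around its own diagonal, as a true
  x-drop extension would behave. Ties among maximal alignments are
  broken deterministically (smallest query start, then subject start).
* **Significance.** Ungapped Karlin–Altschul statistics:
  E = K·m·n·e^(−λS) with m the query length (in the compared alphabet),
  n the total database residues, λ the unique positive root of
  Σ pᵢpⱼe^(λsᵢⱼ) = 1 (solved to residual < 1e-9), and K computed by the
  standard convolution series for integer-score schemes. Both are
  derived from the scoring scheme at run time and are user-overridable.
  The companion bit score is (λS − ln K)/ln 2.

### Why these defaults

* Nucleotide scoring +1/−2 with affine gaps −5 (open) / −2 (extend).
  An early design used a linear −2 gap cost; testing showed that with a
  zero opening cost a single-gap column is no more expensive than a
  mismatch, so random *gapped* alignments systematically exceed the
  cutoff that ungapped E-value theory implies — at the 1e-5 cutoff this
  produced on the order of one false candidate per 10,000 random
  100-mers against a 30 kb database. Affine opening, the convention in
  production nucleotide aligners, restores the approximate validity of
  the ungapped statistics. Protein mode uses BLOSUM62 with −11/−1.
* K computed exactly rather than approximated. A fixed K = 0.1 was
  considered and rejected: it understates E-values about six-fold,
  which silently admits score-19 random hits at the nominal 1e-5
  threshold. The computed value for +1/−2 with uniform base frequencies
  is 0.621 (matching the published constant for this scheme); the
  implementation is validated against the closed form (q−p)²/q = 1/3
  for the ±1 scheme.
* Remaining approximations, stated: the search space is raw m·n with no
  edge-effect or length correction; gapped alignments are scored with
  ungapped λ and K; in translated mode m is the read length in codons.
  E-values from the built-in searcher are therefore approximate — used
  for thresholding and ranking, not as calibrated probabilities — and
  a small excess of borderline random hits over the nominal expectation
  remains possible.

## Tool-agreement statistics

When two tools classify the same read universe, `compare_runs()` builds
the 2×2 table (a = both positive, b = first-only, c = second-only,
d = both negative) and computes:

* **Cohen's kappa** κ = (p₀ − pₑ)/(1 − pₑ), with p₀ = (a+d)/N and
  pₑ = ((a+b)(a+c) + (c+d)(b+d))/N²; defined as 1 for the degenerate
  table where both raters are constant and identical.
* **Yates-corrected chi-square** on the positive proportions (1 df,
  upper tail), via `stats::chisq.test(correct = TRUE)` after checking
  all expected counts are positive. "Corrected chi-square" is read as
  the Yates continuity correction, its standard meaning in the
  epidemiologic calculators this comparison style comes from.
* The comparison arithmetic: extra reads b, percent increase 100·b/a
  (reported when c = 0, rounded to integer), and the fold-ratio of an
  unconfirmed raw match count over the confirmed positives — the
  overestimation factor one would incur by skipping the RBH step.

Positive proportions are rendered at two decimals (e.g. 1,110 of
1,636,697 reads renders "0.07%"); full precision is kept in the
machine-readable summary.

## The simulator: what it emulates and what it does not

`generate_metagenome()` produces a read set with a per-read truth table
(origin, source coordinates, strand, substitution and ambiguity counts,
duplicate flags) from a single integer seed, so identical parameters
give byte-identical output. Background reads are i.i.d. bases at a
configurable GC content (default 0.5) — a deliberately simple,
auditable null for false-positive testing, not a Markov or
community-abundance model. Planted reads are uniform random substrings
of the supplied source sequences, forward or reverse-complement with
probability 0.5 (exercising minus-strand hit encoding), then mutated
position-wise (substitution, then N-masking) and optionally re-emitted
as duplicates under fresh ids.

Defaults describe the desk-scale benchmark used throughout the tests:
10,000 background + 200 planted reads of 100 nt, 1% substitutions, 0.5%
N positions, 5% duplication. These sizes keep the full test suite fast
while leaving the statistical properties (seed specificity, binomial
mutation counts) testable; they are the package's chosen study
conditions, not limits of the implementation. What passing these tests
does *not* show: behaviour on real sequencer error profiles (indels,
quality-correlated errors), on skewed community compositions, or at the
search-space sizes of comprehensive reference databases, where absolute
E-values scale very differently.

One property of small search spaces deserves emphasis: against a ~30 kb
query set, a chance ~23-nt near-exact identity between a random read
and the query set is genuinely significant (E ≈ 1e-6) and occurs in
roughly one random 100-mer per 10,000–50,000. Such reads are *correct*
positives of the method as specified — significance is relative to the
search space — and the simulator's specificity tests therefore assert
zero background hits across most, but not all, seeds.

## Numerical and degenerate-input choices

* Thresholds are strict inequalities ("shorter than 40", "more than
  20%"), read literally.
* Duplicate removal keeps the first occurrence (`remove-all` available):
  discarding every copy would throw away the most abundant, often most
  informative, sequences.
* `best_hit` tie rules (E-value, bit score, subject id) make
  classification independent of hit-table order; cross-taxon exact ties
  are declared `ambiguous` rather than positive.
* Empty inputs: cleaning an empty read set yields an empty set and a
  zeroed report; a summary over zero processed reads reports a 0%
  positive fraction without dividing by zero; an empty hit table is a
  valid (empty) search result, and the pipeline completes with zero
  candidates.
* Root-finding for λ brackets the positive root by doubling and solves
  to 1e-12, rejecting schemes with non-negative expected score; the K
  series is truncated at term < 1e-12.
* FASTQ parsing is 4-line-block structured, so `@` at the start of a
  quality line cannot be misread as a header.

## Known limitations

* The built-in searcher is a correct desk-scale reference, not a
  replacement for a production aligner: no two-hit seeding, no gapped
  X-drop heuristic, no composition-based statistics, single-threaded.
  For real metagenomes, run an external aligner and ingest its tabular
  output.
* Taxonomy is best-hit only — no lowest-common-ancestor voting, no
  abundance estimation, by design.
* Quality-aware trimming, adapter removal and SRA container handling
  are out of scope; inputs are FASTA/FASTQ.
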