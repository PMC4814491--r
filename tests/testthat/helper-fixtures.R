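# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no fixture files are stored.

random_records <- function(n, len = c(40L, 120L), seed = 1L,
                           alphabet = c("A", "C", "G", "T")) {
  withr::with_seed(seed, {
    lens <- sample(len[[1L]]:len[[length(len)]], n, replace = TRUE)
    data.frame(
      id = sprintf("r%04d", seq_len(n)),
      description = ifelse(seq_len(n) %% 3L == 0L,
                           paste0("sample=", sample(letters, n, TRUE)), ""),
      sequence = vapply(lens, function(L) {
        paste(sample(alphabet, L, replace = TRUE), collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE)
  })
}

random_hit_frame <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    qs <- sample.int(200, n, replace = TRUE)
    alen <- sample.int(150, n, replace = TRUE) + 10L
    data.frame(
      query_id = sprintf("read%03d", sample.int(50, n, replace = TRUE)),
      subject_id = sprintf("subj%02d", sample.int(9, n, replace = TRUE)),
      percent_identity = round(stats::runif(n, 60, 100), 2),
      alignment_length = alen,
      mismatches = sample.int(10, n, replace = TRUE) - 1L,
      gap_opens = sample.int(3, n, replace = TRUE) - 1L,
      q_start = qs, q_end = qs + alen - 1L,
      s_start = sample.int(5000, n, replace = TRUE),
      s_end = sample.int(5000, n, replace = TRUE),
      evalue = 10^stats::runif(n, -50, -1),
      bit_score = round(stats::runif(n, 30, 300), 1),
      stringsAsFactors = FALSE)
  })
}

# independent full-matrix Smith-Waterman oracle via Biostrings
oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  Biostrings::score(pa)
}

shares_kmer <- function(a, b, k = 11L) {
  ka <- substring(a, seq_len(nchar(a) - k + 1L), seq_len(nchar(a) - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(nchar(b) - k + 1L), seq_len(nchar(b) - k + 1L) + k - 1L)
  any(ka %in% kb)
}

# raw alignment score recovered from a reported bit score
score_from_bits <- function(bits, lambda, K) {
  (bits * log(2) + log(K)) / lambda
}

write_taxa_file <- function(ids, taxa, is_target, path) {
  write.table(data.frame(ids, taxa, as.integer(is_target)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}
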