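test_that("smith_waterman handles perfect match and no-match cases", {
  sc <- scoring_scheme("nucleotide", match = 1, mismatch = -3,
                       gap_open = 0, gap_extend = -5)
  a <- smith_waterman("ACGTACGT", "ACGTACGT", sc)
  expect_equal(a$score, 8)
  expect_identical(a$aligned_query, "ACGTACGT")
  expect_identical(c(a$q_start, a$q_end, a$s_start, a$s_end), c(1L, 8L, 1L, 8L))

  z <- smith_waterman("AAAA", "CCCC", sc)
  expect_equal(z$score, 0)
  expect_identical(z$aligned_query, "")
})

test_that("smith_waterman reproduces the classic gapped example", {
  # match +3 / mismatch -3 / linear gap -2; expected alignment GTT-AC/GTTGAC
  sc <- scoring_scheme("nucleotide", match = 3, mismatch = -3,
                       gap_open = 0, gap_extend = -2)
  a <- smith_waterman("TGTTACGG", "GGTTGACTA", sc)
  expect_equal(a$score, 13)
  expect_identical(a$aligned_query, "GTT-AC")
  expect_identical(a$aligned_subject, "GTTGAC")
  expect_identical(c(a$q_start, a$q_end, a$s_start, a$s_end),
                   c(2L, 6L, 2L, 7L))
  expect_equal(oracle_local_score("TGTTACGG", "GGTTGACTA", match = 3,
                                  mismatch = -3, gap_open = 0,
                                  gap_extend = 2), 13)
})

test_that("smith_waterman agrees with an independent aligner on random pairs", {
  sc <- scoring_scheme("nucleotide", match = 1, mismatch = -2,
                       gap_open = 0, gap_extend = -2)
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
      ours <- smith_waterman(a, b, sc)
      expect_equal(ours$score,
                   oracle_local_score(a, b, gap_open = 0, gap_extend = 2),
                   info = paste(a, b))
      # symmetry of the score under symmetric scoring
      expect_equal(smith_waterman(b, a, sc)$score, ours$score)
    }
  })
})

test_that("smith_waterman works with protein scoring (BLOSUM62, affine)", {
  sc <- scoring_scheme("protein")
  a <- smith_waterman("MKVLLTTAY", "MKVLLSTAY", sc)
  expect_gt(a$score, 0)
  pa <- Biostrings::pairwiseAlignment(
    "MKVLLTTAY", "MKVLLSTAY", type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  expect_equal(a$score, Biostrings::score(pa))
  expect_error(smith_waterman("MKJ1", "MKV", sc), "not covered")
})

test_that("alignment score is recomputable from the aligned strings", {
  sc <- scoring_scheme("nucleotide", match = 2, mismatch = -3,
                       gap_open = -4, gap_extend = -1)
  withr::with_seed(21, {
    for (i in 1:10) {
      a <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
      al <- smith_waterman(a, b, sc)
      if (al$score == 0) next
      qs <- strsplit(al$aligned_query, "")[[1]]
      ss <- strsplit(al$aligned_subject, "")[[1]]
      col_scores <- ifelse(qs == "-" | ss == "-", 0,
                           sc$matrix[cbind(match(qs, sc$alphabet),
                                           match(ss, sc$alphabet))])
      gap_runs <- function(g) {
        r <- rle(g); sum(r$values)
      }
      gap_cost <- sc$gap_open * (gap_runs(qs == "-") + gap_runs(ss == "-")) +
        sc$gap_extend * sum(qs == "-" | ss == "-")
      expect_equal(sum(col_scores) + gap_cost, al$score)
    }
  })
})

test_that("six-frame translation follows the standard code", {
  tf <- translate_frames("ATGAAA")
  expect_identical(tf$peptide[tf$frame == 1L], "MK")
  expect_identical(translate_frames("TAA")$peptide[[1L]], "*")
  expect_error(translate_frames("AT"), "codon")

  # frame -1 equals frame +1 of the reverse complement
  withr::with_seed(5, {
    for (i in 1:5) {
      s <- paste(sample(c("A", "C", "G", "T"), 31, TRUE), collapse = "")
      expect_identical(translate_frames(s)$peptide[[4L]],
                       translate_frames(reverse_complement(s))$peptide[[1L]])
    }
  })
})

test_that("karlin_lambda matches closed forms and rejects invalid schemes", {
  s11 <- scoring_scheme("nucleotide", match = 1, mismatch = -1)
  expect_equal(karlin_lambda(s11), log(3), tolerance = 1e-9)

  s12 <- scoring_scheme("nucleotide", match = 1, mismatch = -2)
  lam <- karlin_lambda(s12)
  expect_equal(lam, log((3 + sqrt(21)) / 2), tolerance = 1e-9)
  # residual of the defining equation below 1e-9
  p <- rep(0.25, 4)
  S <- s12$matrix[1:4, 1:4]
  expect_lt(abs(sum(outer(p, p) * exp(lam * S)) - 1), 1e-9)

  s10 <- scoring_scheme("nucleotide", match = 1, mismatch = 0)
  expect_error(karlin_lambda(s10), "no valid lambda")
})

test_that("evalue obeys its algebraic identities", {
  expect_equal(evalue(0, 1, 1, lambda = log(2), K = 1), 1)
  e1 <- evalue(30, 100, 1e6, lambda = 1.33, K = 0.1)
  expect_equal(evalue(30, 100, 2e6, lambda = 1.33, K = 0.1), 2 * e1)
  # strictly decreasing in S
  S <- 0:50
  ev <- evalue(S, 100, 1e6, lambda = 1.1, K = 0.1)
  expect_true(all(diff(ev) < 0))
  # E = 1 exactly when the bit score equals log2(m n)
  bits <- bit_score(S, lambda = 1.1, K = 0.1)
  expect_equal(ev, 100 * 1e6 * 2^(-bits))
})

test_that("seeded_search finds verbatim substrings at full identity", {
  db <- random_sources(n = 2, length = 2000, seed = 31)
  frag <- substr(db$sequence[[1L]], 501, 600)
  reads <- data.frame(id = c("hit_read", "null_read"), description = "",
                      sequence = c(frag, strrep("AC", 50)),
                      stringsAsFactors = FALSE)
  hits <- seeded_search(reads, db, search_params())
  h <- hits[hits$query_id == "hit_read", ]
  expect_gte(nrow(h), 1L)
  expect_true(any(h$percent_identity == 100 & h$q_start == 1 &
                    h$q_end == 100))
  expect_true(any(h$s_start == 501 & h$s_end == 600))
  # poly-AC read shares no 11-mer with the random database
  expect_false("null_read" %in% hits$query_id)
})

test_that("seeded_search encodes minus-strand matches with s_start > s_end", {
  db <- random_sources(n = 1, length = 1500, seed = 8)
  frag <- reverse_complement(substr(db$sequence[[1L]], 201, 320))
  reads <- data.frame(id = "rc_read", description = "", sequence = frag,
                      stringsAsFactors = FALSE)
  hits <- seeded_search(reads, db, search_params())
  expect_gte(nrow(hits), 1L)
  expect_true(any(hits$s_start > hits$s_end))
  best <- hits[which.min(hits$evalue), ]
  expect_identical(c(best$s_start, best$s_end), c(320L, 201L))
})

test_that("seeded_search recovers every seeded above-cutoff oracle alignment", {
  # 30 reads vs 3 short subjects; oracle = exhaustive local alignment
  withr::with_seed(77, {
    subjects <- random_sources(n = 3, length = 500, seed = 123)
    reads <- lapply(1:30, function(i) {
      if (i <= 15) {
        s <- subjects$sequence[[(i %% 3) + 1L]]
        start <- sample.int(400, 1)
        frag <- substr(s, start, start + 79L)
        # a few substitutions away from the source
        mutate_sequence(frag, substitution_rate = 0.03)$sequence
      } else {
        paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
      }
    })
    reads <- data.frame(id = sprintf("rd%02d", 1:30), description = "",
                        sequence = unlist(reads), stringsAsFactors = FALSE)
  })
  params <- search_params()
  hits <- seeded_search(reads, subjects, params)
  lambda <- karlin_lambda(scoring_scheme("nucleotide"))
  KK <- karlin_K(scoring_scheme("nucleotide"), lambda)
  n_db <- sum(nchar(subjects$sequence))
  n_checked <- 0L
  for (r in seq_len(nrow(reads))) {
    for (s in seq_len(nrow(subjects))) {
      rs <- reads$sequence[[r]]
      ss <- subjects$sequence[[s]]
      if (!shares_kmer(rs, ss, 11L)) next
      sc <- oracle_local_score(rs, ss)
      ev <- evalue(sc, nchar(rs), n_db, lambda, KK)
      if (ev > params$evalue_cutoff) next
      n_checked <- n_checked + 1L
      h <- hits[hits$query_id == reads$id[[r]] &
                  hits$subject_id == subjects$id[[s]] &
                  hits$s_start < hits$s_end, ]
      expect_gte(nrow(h), 1L)
      ours <- score_from_bits(h$bit_score, lambda, KK)
      expect_true(any(abs(ours - sc) < 1e-6),
                  info = sprintf("read %s vs %s: oracle %g, ours %s",
                                 reads$id[[r]], subjects$id[[s]], sc,
                                 paste(round(ours, 3), collapse = ",")))
    }
  }
  expect_gte(n_checked, 10L)  # the fixture really exercises the harness
})

test_that("translated-mode hits map to codon-aligned read coordinates", {
  src <- random_sources(n = 1, length = 1200, seed = 55)
  pep <- translate_frames(substr(src$sequence[[1L]], 1, 900))$peptide[[1L]]
  pep <- gsub("*", "", pep, fixed = TRUE)
  db <- data.frame(id = "prot1", description = "", sequence = pep,
                   stringsAsFactors = FALSE)
  sim <- generate_metagenome(simulation_params(
    n_background = 5, n_planted = 10, read_length = 120,
    sources = data.frame(id = "src", description = "",
                         sequence = substr(src$sequence[[1L]], 1, 900),
                         stringsAsFactors = FALSE),
    substitution_rate = 0, ambiguity_rate = 0, duplication_fraction = 0,
    seed = 4))
  hits <- seeded_search(sim$records, db,
                        search_params(mode = "auto", evalue_cutoff = 1e-3))
  expect_gt(nrow(hits), 0L)
  read_len <- setNames(nchar(sim$records$sequence), sim$records$id)
  expect_true(all(hits$q_start >= 1 &
                    hits$q_end <= read_len[hits$query_id]))
  expect_true(all((hits$q_end - hits$q_start + 1L) %% 3L == 0L))
  expect_true(all(hits$s_start <= hits$s_end))  # protein subject coordinates
})

test_that("mode resolution and degenerate databases behave as specified", {
  nt_db <- random_sources(n = 1, length = 200, seed = 2)
  expect_error(seeded_search(nt_db[0, ], nt_db[0, ], search_params()),
               "empty database")
  short_db <- data.frame(id = "s", description = "", sequence = "ACGTACGT",
                         stringsAsFactors = FALSE)
  expect_error(seeded_search(nt_db, short_db, search_params(k = 21)),
               "exceeds every database sequence")
})

test_that("run_search filters external tables at the cutoff", {
  reads <- data.frame(id = c("r1", "r2"), description = "",
                      sequence = c(strrep("ACGT", 20), strrep("GGCA", 20)),
                      stringsAsFactors = FALSE)
  hits <- random_hit_frame(2, seed = 9)
  hits$query_id <- c("r1", "r2")
  hits$evalue <- c(1e-6, 1e-4)
  f <- withr::local_tempfile()
  write_hit_table(hits, f)
  out <- run_search(reads, params = search_params(evalue_cutoff = 1e-5),
                    external_hits = f)
  expect_identical(out$query_id, "r1")

  # disjoint id universes warn and may return empty
  hits$query_id <- c("x1", "x2")
  write_hit_table(hits, f)
  expect_warning(out2 <- run_search(reads, params = search_params(),
                                    external_hits = f),
                 "no query ids")
  expect_identical(nrow(out2), 0L)
})

test_that("builtin and external-ingestion modes agree on the same fixture", {
  db <- random_sources(n = 2, length = 2000, seed = 13)
  sim <- generate_metagenome(simulation_params(
    n_background = 100, n_planted = 20, read_length = 100, sources = db,
    substitution_rate = 0, ambiguity_rate = 0, duplication_fraction = 0,
    seed = 6))
  params <- search_params()
  builtin <- run_search(sim$records, db, params)
  f <- withr::local_tempfile()
  write_hit_table(builtin, f)
  external <- run_search(sim$records, params = params, external_hits = f)
  expect_identical(select_candidates(external, 1e-5),
                   select_candidates(builtin, 1e-5))
  planted <- sim$truth$read_id[sim$truth$origin == "planted"]
  expect_setequal(select_candidates(builtin, 1e-5), planted)
})
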