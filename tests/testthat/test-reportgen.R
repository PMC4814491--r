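test_that("cohen_kappa matches definition and handles degenerate tables", {
  expect_equal(cohen_kappa(50, 0, 0, 50), 1)
  expect_equal(cohen_kappa(25, 25, 25, 25), 0)
  # constant identical raters agree perfectly by definition
  expect_equal(cohen_kappa(100, 0, 0, 0), 1)
  expect_equal(cohen_kappa(0, 0, 0, 10), 1)
  # one constant rater, the other all-opposite: no chance agreement
  expect_equal(cohen_kappa(0, 0, 10, 0), 0)

  # independent implementation cross-check on random tables
  withr::with_seed(10, {
    for (i in 1:25) {
      ct <- sample.int(200, 4)
      k <- cohen_kappa(ct[1], ct[2], ct[3], ct[4])
      tab <- matrix(ct, 2, byrow = TRUE)
      expect_equal(k, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
      expect_gte(k, -1)
      expect_lte(k, 1)
      # invariance under simultaneous row/column label swap
      expect_equal(k, cohen_kappa(ct[4], ct[3], ct[2], ct[1]))
    }
  })
})

test_that("corrected chi-square applies the Yates correction", {
  same <- matrix(c(10, 10, 90, 90), 2)
  res <- corrected_chisq(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # textbook Yates formula as the second route
  tab <- matrix(c(10, 20, 90, 80), 2)
  res2 <- corrected_chisq(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  yates <- sum((abs(tab - expected) - 0.5)^2 / expected)
  expect_equal(res2$statistic, yates, tolerance = 1e-12)
  expect_equal(res2$p_value, stats::pchisq(yates, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # Yates statistic never exceeds the uncorrected one
  withr::with_seed(12, {
    for (i in 1:20) {
      t2 <- matrix(sample.int(500, 4) + 5L, 2)
      corr <- corrected_chisq(t2)$statistic
      uncorr <- suppressWarnings(
        stats::chisq.test(t2, correct = FALSE)$statistic)
      expect_lte(corr, unname(uncorr) + 1e-12)
    }
  })

  expect_error(corrected_chisq(matrix(c(0, 0, 5, 5), 2)), "zero expected")
})

test_that("compare_runs builds the table and agreement statistics", {
  universe <- sprintf("r%03d", 1:100)
  a <- setNames(rep("neg", 100), universe)
  b <- a
  a[1:30] <- "pos"
  b[1:25] <- "pos"
  res <- compare_runs(a, b)
  expect_identical(unname(res$contingency), c(25L, 5L, 0L, 70L))
  expect_equal(res$percent_increase, round(100 * 5 / 25))
  expect_equal(res$extra_reads, 5L)

  # identical classifications: perfect agreement
  same <- compare_runs(a, a)
  expect_equal(same$kappa, 1)
  expect_equal(same$percent_increase, 0)

  # order of the read universe must not matter
  res2 <- compare_runs(a, b[sample(names(b))])
  expect_identical(res2$contingency, res$contingency)

  expect_error(compare_runs(a, b[1:99]), "identical read universe")
})

test_that("proportion rendering follows the two-decimal policy", {
  expect_identical(format_percent(1110, 1636697), "0.07%")
  expect_identical(format_percent(185, 29117), "0.64%")
  expect_identical(format_percent(0, 0), "0.00%")
  expect_identical(format_percent(1, 2, digits = 1), "50.0%")
})

test_that("run summaries conserve counts and render correctly", {
  cls <- data.frame(read_id = c("a", "b", "c"),
                    status = c("positive", "positive", "negative"),
                    best_subject_id = c("v1", "v2", "d"),
                    best_evalue = 1e-9, best_bit_score = 60,
                    best_taxon = c("Mimiviridae", "Mimiviridae", "cellular"),
                    stringsAsFactors = FALSE)
  s <- summarize_run("mg1", n_processed = 100,
                     candidates = c("a", "b", "c"), classifications = cls,
                     duration = 1.5, cpu_count = 2)
  expect_identical(s$n_positive, 2L)
  expect_identical(s$n_candidates, 3L)
  expect_equal(sum(unlist(s$per_taxon)), s$n_positive)
  expect_equal(s$positive_fraction, 2)
  expect_identical(s$matched_query_ids, c("v1", "v2"))

  empty <- summarize_run("mg0", 0, character(), cls[0, ])
  expect_equal(empty$positive_fraction, 0)
})

test_that("write_outputs emits the four files consistently", {
  db <- random_sources(n = 1, length = 1500, seed = 29)
  sim <- generate_metagenome(simulation_params(
    n_background = 40, n_planted = 5, read_length = 100, sources = db,
    substitution_rate = 0, ambiguity_rate = 0, duplication_fraction = 0,
    seed = 9))
  taxa <- taxon_map(db$id, "Mimiviridae", "Mimiviridae", query_ids = db$id)
  step2 <- seeded_search(sim$records, db, search_params())
  cand <- select_candidates(step2, 1e-5)
  cls <- classify_reads(step2, taxa, cand)
  s <- summarize_run("sim", nrow(sim$records), cand, cls)
  dir <- withr::local_tempdir()
  paths <- write_outputs(dir, step2, step2, cls, sim$records, s)

  # file 3 contains exactly the positive reads
  pos_ids <- cls$read_id[cls$status == "positive"]
  fasta <- read_sequences(paths[["positives"]])
  expect_setequal(fasta$id, pos_ids)
  planted <- sim$truth$read_id[sim$truth$origin == "planted"]
  expect_setequal(fasta$id, planted)

  # file 1 is the step-2 table pass-through (modulo numeric formatting)
  back <- read_hit_table(paths[["step2"]])
  expect_identical(back$query_id, step2$query_id)
  expect_identical(back$subject_id, step2$subject_id)

  # file 2 restricted to positive reads
  pos_hits <- read_hit_table(paths[["positive_hits"]])
  expect_true(all(pos_hits$query_id %in% pos_ids))

  js <- jsonlite::read_json(paths[["summary_json"]])
  expect_identical(js$n_positive, length(pos_ids))

  # zero-positive run leaves files 2 and 3 empty
  dir2 <- withr::local_tempdir()
  cls_neg <- cls
  cls_neg$status <- "negative"
  s0 <- summarize_run("sim", nrow(sim$records), cand, cls_neg)
  p0 <- write_outputs(dir2, step2, step2, cls_neg, sim$records, s0)
  expect_identical(nrow(read_hit_table(p0[["positive_hits"]])), 0L)
  expect_identical(file.size(p0[["positives"]]), 0)
  js0 <- jsonlite::read_json(p0[["summary_json"]])
  expect_identical(js0$n_positive, 0L)
})
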