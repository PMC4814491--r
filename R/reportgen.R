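#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between two binary classifications:
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with observed agreement
#' \eqn{p_o = (a+d)/N} and chance agreement
#' \eqn{p_e = ((a+b)(a+c) + (c+d)(b+d))/N^2}. When both raters are
#' constant and identical (degenerate table with \eqn{p_e = 1} and
#' \eqn{p_o = 1}) kappa is defined as 1.
#'
#' @param a Both-positive count.
#' @param b First-rater-only positive count.
#' @param c Second-rater-only positive count.
#' @param d Both-negative count.
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohen_kappa(50, 0, 0, 50)   # 1
#' cohen_kappa(25, 25, 25, 25) # 0
cohen_kappa <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  N <- sum(counts)
  po <- (a + d) / N
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / N^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    if (abs(1 - po) < .Machine$double.eps * 4) return(1)
    stop("degenerate agreement table: chance agreement is 1 but observed ",
         "agreement is not", call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Chi-square test of homogeneity with continuity correction, 1 degree of
#' freedom, upper-tail p-value. All expected counts must be positive.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return A list with `statistic` and `p_value`.
#' @export
corrected_chisq <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("zero expected count in contingency table", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Compare two binary read classifications
#'
#' Builds the 2x2 contingency table over a shared read universe, computes
#' Cohen's kappa and the Yates-corrected chi-square on the positive
#' proportions, and the comparison arithmetic used when benchmarking one
#' annotation tool against another: the extra reads found by tool A only,
#' the percent increase over the shared positives (when tool B finds
#' nothing exclusively), and the fold-ratio of tool B's raw (unconfirmed)
#' match count over tool A's confirmed positives.
#'
#' @param labels_a,labels_b Named character vectors (`"pos"`/`"neg"`) or
#'   named logical vectors over the identical read universe, named by
#'   read id.
#' @param raw_count_b Optional raw match count reported by tool B before
#'   any confirmation, for the fold-ratio.
#' @return A list of class `agreement_result`: `contingency` (a, b, c, d),
#'   `kappa`, `chi2_corrected`, `p_value`, `extra_reads`,
#'   `percent_increase` (rounded to nearest integer; `NA` unless c = 0),
#'   `fold_ratio` (rounded; `NA` unless `raw_count_b` given).
#' @export
compare_runs <- function(labels_a, labels_b, raw_count_b = NULL) {
  if (is.logical(labels_a)) labels_a <- ifelse(labels_a, "pos", "neg")
  if (is.logical(labels_b)) labels_b <- ifelse(labels_b, "pos", "neg")
  if (is.null(names(labels_a)) || is.null(names(labels_b)) ||
      !setequal(names(labels_a), names(labels_b)) ||
      length(labels_a) != length(labels_b)) {
    stop("classifications must cover the identical read universe",
         call. = FALSE)
  }
  labels_b <- labels_b[names(labels_a)]
  pa <- labels_a == "pos"
  pb <- labels_b == "pos"
  a <- sum(pa & pb); b <- sum(pa & !pb); c <- sum(!pa & pb); d <- sum(!pa & !pb)
  agreement_result(a, b, c, d, raw_count_b)
}

#' @rdname compare_runs
#' @param a,b,c,d Contingency counts (both-positive, A-only, B-only,
#'   both-negative), for building the result directly from published
#'   counts rather than per-read labels.
#' @export
agreement_result <- function(a, b, c, d, raw_count_b = NULL) {
  N <- a + b + c + d
  tab <- matrix(c(a + b, c + a, N - a - b, N - c - a), nrow = 2)
  # rows: tools; cols: positive / negative proportions over the universe
  chi <- corrected_chisq(tab)
  structure(list(
    contingency = c(a = a, b = b, c = c, d = d),
    kappa = cohen_kappa(a, b, c, d),
    chi2_corrected = chi$statistic,
    p_value = chi$p_value,
    extra_reads = b,
    percent_increase = if (c == 0 && a > 0) round(100 * b / a) else NA_real_,
    fold_ratio = if (!is.null(raw_count_b) && (a + b) > 0) {
      round(raw_count_b / (a + b))
    } else NA_real_),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  ct <- x$contingency
  cat("Tool agreement\n")
  cat(sprintf("  both positive: %d | A only: %d | B only: %d | both negative: %d\n",
              ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]]))
  cat(sprintf("  Cohen's kappa: %.3f\n", x$kappa))
  cat(sprintf("  corrected chi-square: %.3f (p = %.2g)\n",
              x$chi2_corrected, x$p_value))
  if (!is.na(x$percent_increase)) {
    cat(sprintf("  extra reads by A: %d (%d%% more)\n", x$extra_reads,
                x$percent_increase))
  }
  if (!is.na(x$fold_ratio)) {
    cat(sprintf("  raw/confirmed fold ratio: %d\n", x$fold_ratio))
  }
  invisible(x)
}

#' Render a proportion as a percentage string
#'
#' @param n Numerator count.
#' @param total Denominator count; 0 renders as 0.00%.
#' @param digits Decimals (default 2).
#' @return Character, e.g. `"0.07%"`.
#' @export
format_percent <- function(n, total, digits = 2L) {
  frac <- if (total == 0) 0 else 100 * n / total
  sprintf(paste0("%.", digits, "f%%"), frac)
}

#' Summarize a pipeline run
#'
#' @param metagenome_id Label for the analysed metagenome.
#' @param n_processed Reads entering the search (after cleaning).
#' @param candidates Candidate read ids (first-pass survivors).
#' @param classifications Output of [classify_reads()].
#' @param duration Wall-clock seconds of the run.
#' @param cpu_count CPUs used.
#' @param parameters Named list: the effective configuration snapshot.
#' @return A list of class `run_summary` with counts, the positive
#'   fraction (percent, full precision), per-taxon tallies and the ids of
#'   the matched query/reference sequences.
#' @export
summarize_run <- function(metagenome_id, n_processed, candidates,
                          classifications, duration = NA_real_,
                          cpu_count = 1L, parameters = list()) {
  tal <- tally_by_taxon(classifications)
  n_positive <- tal$total
  n_candidates <- length(candidates)
  stopifnot(n_positive <= n_candidates, n_candidates <= n_processed)
  pos <- classifications[classifications$status == "positive", , drop = FALSE]
  structure(list(
    metagenome_id = metagenome_id,
    n_processed = as.integer(n_processed),
    n_candidates = as.integer(n_candidates),
    n_positive = as.integer(n_positive),
    positive_fraction = if (n_processed == 0) 0 else
      100 * n_positive / n_processed,
    per_taxon = as.list(tal$per_taxon),
    matched_query_ids = sort(unique(pos$best_subject_id)),
    duration = duration,
    cpu_count = as.integer(cpu_count),
    parameters = parameters), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}

render_summary <- function(x) {
  lines <- c(
    paste0("metagenome: ", x$metagenome_id),
    paste0("reads processed: ", x$n_processed),
    paste0("candidate reads extracted: ", x$n_candidates),
    paste0("reads with a query sequence as best hit: ", x$n_positive,
           " (", format_percent(x$n_positive, x$n_processed), ")"),
    if (length(x$per_taxon)) {
      paste0("  ", names(x$per_taxon), ": ", unlist(x$per_taxon))
    },
    paste0("matched query sequences: ",
           if (length(x$matched_query_ids)) {
             paste(x$matched_query_ids, collapse = ", ")
           } else "none"),
    paste0("duration (s): ",
           if (is.na(x$duration)) "NA" else sprintf("%.1f", x$duration)),
    paste0("CPUs: ", x$cpu_count))
  lines
}

#' Write the pipeline's output files
#'
#' Emits the four result files of a run into `dir`:
#' `step2_hits.tsv` (the raw first-pass hit table for reads matching a
#' query sequence), `positive_hits.tsv` (the reference hit table
#' restricted to confirmed-positive reads), `positives.fasta` (the
#' confirmed reads themselves) and `summary.txt` / `summary.json` (the
#' run summary, human- and machine-readable). A fifth file,
#' `classifications.tsv`, records the per-read verdicts including
#' ambiguous and unresolved reads.
#'
#' @param dir Output directory (created if needed).
#' @param step2_hits First-pass hit table.
#' @param step3_hits Reference hit table.
#' @param classifications Output of [classify_reads()].
#' @param reads Read data frame the candidates were drawn from.
#' @param summary A [summarize_run()] object.
#' @return Named character vector of the file paths, invisibly.
#' @export
write_outputs <- function(dir, step2_hits, step3_hits, classifications,
                          reads, summary) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(step2 = file.path(dir, "step2_hits.tsv"),
             positive_hits = file.path(dir, "positive_hits.tsv"),
             positives = file.path(dir, "positives.fasta"),
             summary_txt = file.path(dir, "summary.txt"),
             summary_json = file.path(dir, "summary.json"),
             classifications = file.path(dir, "classifications.tsv"))
  write_hit_table(step2_hits, paths[["step2"]])
  pos_ids <- classifications$read_id[classifications$status == "positive"]
  write_hit_table(step3_hits[step3_hits$query_id %in% pos_ids, , drop = FALSE],
                  paths[["positive_hits"]])
  write_fasta(reads[reads$id %in% pos_ids, , drop = FALSE],
              paths[["positives"]])
  writeLines(render_summary(summary), paths[["summary_txt"]])
  js <- unclass(summary)
  js$positive_fraction_rendered <- format_percent(summary$n_positive,
                                                  summary$n_processed)
  jsonlite::write_json(js, paths[["summary_json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  cls <- classifications
  write.table(cls, paths[["classifications"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
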