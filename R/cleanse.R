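#' Cleaning parameters
#'
#' Thresholds for the read-cleaning step. Defaults mirror common practice
#' for raw metagenome read sets: drop exact duplicate reads, reads shorter
#' than 40 nucleotides, and reads where more than 20% of positions are
#' ambiguous.
#'
#' @param min_length Minimum read length in nucleotides; reads strictly
#'   shorter are removed. Default 40.
#' @param max_ambiguity_frac Maximum tolerated fraction of ambiguous
#'   positions; reads strictly above are removed. Default 0.20.
#' @param dedup Remove duplicated reads? Default `TRUE`.
#' @param dedup_policy `"keep-one"` (default) keeps the first occurrence of
#'   each duplicated sequence; `"remove-all"` drops every copy.
#' @param ambiguity_chars Characters counted as ambiguous, or `NULL`
#'   (default) to count every non-ACGT letter (N plus the IUPAC
#'   degeneracy codes). Pass `"N"` to count only N.
#' @return A list of class `cleaning_params`.
#' @export
cleaning_params <- function(min_length = 40L, max_ambiguity_frac = 0.20,
                            dedup = TRUE,
                            dedup_policy = c("keep-one", "remove-all"),
                            ambiguity_chars = NULL) {
  stopifnot(min_length >= 1, max_ambiguity_frac >= 0, max_ambiguity_frac <= 1)
  structure(list(min_length = as.integer(min_length),
                 max_ambiguity_frac = max_ambiguity_frac,
                 dedup = isTRUE(dedup),
                 dedup_policy = match.arg(dedup_policy),
                 ambiguity_chars = ambiguity_chars),
            class = "cleaning_params")
}

#' Fraction of ambiguous positions in a sequence
#'
#' For nucleotide data every non-ACGT letter (N and the IUPAC degeneracy
#' codes R, Y, S, W, K, M, B, D, H, V) counts as ambiguous.
#'
#' @param sequence Character vector of sequences (non-empty).
#' @param ambiguity_chars Optional character vector restricting which
#'   letters count as ambiguous (e.g. `"N"`).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
#' @examples
#' ambiguity_fraction(c("ACGT", "ACGTN", "NRYSW"))  # 0, 0.2, 1
ambiguity_fraction <- function(sequence, ambiguity_chars = NULL) {
  if (any(!nzchar(sequence))) {
    stop("ambiguity_fraction: empty sequence", call. = FALSE)
  }
  s <- toupper(sequence)
  n_amb <- if (is.null(ambiguity_chars)) {
    nchar(gsub("[ACGT]", "", s))
  } else {
    chars <- paste(toupper(ambiguity_chars), collapse = "")
    nchar(s) - nchar(gsub(paste0("[", chars, "]"), "", s))
  }
  n_amb / nchar(s)
}

#' Clean a read set
#'
#' Applies the three removal rules in order — duplicate, then length, then
#' ambiguity — attributing each removed read to the first rule it
#' violates, so the report counts are well defined. Duplicate means exact
#' full-length sequence equality (case-insensitive, forward strand only);
#' under the default keep-one policy the first occurrence is retained.
#' Retained reads keep their input order.
#'
#' @param records Read data frame from [read_sequences()].
#' @param params A [cleaning_params()] object.
#' @return A list with `records` (the retained reads) and `report`, a
#'   `cleaning_report` with the counts `n_input`, `n_removed_duplicate`,
#'   `n_removed_short`, `n_removed_ambiguous`, `n_retained`, `bp_input`
#'   and `bp_retained`.
#' @export
clean_reads <- function(records, params = cleaning_params()) {
  stopifnot(inherits(params, "cleaning_params"))
  if (nrow(records) > 0L) validate_seq_records(records)
  n <- nrow(records)
  if (n == 0L) {
    report <- new_cleaning_report(0L, 0L, 0L, 0L, 0L, 0L, 0L)
    return(list(records = records, report = report))
  }
  seqs <- toupper(records$sequence)
  len <- nchar(seqs)

  is_dup <- if (!params$dedup) {
    rep(FALSE, n)
  } else if (params$dedup_policy == "keep-one") {
    duplicated(seqs)
  } else {
    seqs %in% seqs[duplicated(seqs)]
  }
  is_short <- !is_dup & len < params$min_length
  amb <- ambiguity_fraction(seqs, params$ambiguity_chars)
  is_amb <- !is_dup & !is_short & amb > params$max_ambiguity_frac
  keep <- !(is_dup | is_short | is_amb)

  report <- new_cleaning_report(
    n_input = n,
    n_removed_duplicate = sum(is_dup),
    n_removed_short = sum(is_short),
    n_removed_ambiguous = sum(is_amb),
    n_retained = sum(keep),
    bp_input = sum(len),
    bp_retained = sum(len[keep]))
  list(records = records[keep, , drop = FALSE], report = report)
}

new_cleaning_report <- function(n_input, n_removed_duplicate, n_removed_short,
                                n_removed_ambiguous, n_retained, bp_input,
                                bp_retained) {
  r <- list(n_input = as.integer(n_input),
            n_removed_duplicate = as.integer(n_removed_duplicate),
            n_removed_short = as.integer(n_removed_short),
            n_removed_ambiguous = as.integer(n_removed_ambiguous),
            n_retained = as.integer(n_retained),
            bp_input = as.numeric(bp_input),
            bp_retained = as.numeric(bp_retained))
  stopifnot(r$n_input == r$n_removed_duplicate + r$n_removed_short +
              r$n_removed_ambiguous + r$n_retained,
            r$bp_retained <= r$bp_input)
  structure(r, class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Read cleaning report\n")
  cat(sprintf("  input reads:        %d (%s bp)\n", x$n_input,
              format(x$bp_input, big.mark = ",")))
  cat(sprintf("  removed duplicate:  %d\n", x$n_removed_duplicate))
  cat(sprintf("  removed short:      %d\n", x$n_removed_short))
  cat(sprintf("  removed ambiguous:  %d\n", x$n_removed_ambiguous))
  cat(sprintf("  retained:           %d (%s bp)\n", x$n_retained,
              format(x$bp_retained, big.mark = ",")))
  invisible(x)
}

#' Write a cleaning report as two-column TSV
#'
#' @param report A `cleaning_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  stopifnot(inherits(report, "cleaning_report"))
  df <- data.frame(metric = names(unclass(report)),
                   value = unlist(report, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
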