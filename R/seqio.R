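#' @useDynLib viromine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils head read.delim write.table
NULL

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end",
                 "evalue", "bit_score")

#' Detect the format of a sequence file
#'
#' Looks at the first non-blank character of the input: `>` means FASTA,
#' `@` means FASTQ. Anything else (including an empty file) is an error,
#' since no downstream stage could interpret it.
#'
#' @param path Path to a sequence file, or a character vector of lines
#'   (useful for testing).
#' @return `"fasta"` or `"fastq"`.
#' @export
#' @examples
#' f <- tempfile(); writeLines(c(">r1", "ACGT"), f)
#' detect_format(f)
detect_format <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, n = 50L, warn = FALSE)
  } else {
    as.character(path)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("unrecognized format: input is empty", call. = FALSE)
  }
  first <- substr(trimws(lines[[1L]]), 1L, 1L)
  if (first == ">") return("fasta")
  if (first == "@") return("fastq")
  stop("unrecognized format: first non-blank character is '", first,
       "' (expected '>' for FASTA or '@' for FASTQ)", call. = FALSE)
}

new_seq_records <- function(id = character(), description = character(),
                            sequence = character()) {
  data.frame(id = as.character(id),
             description = as.character(description),
             sequence = as.character(sequence),
             stringsAsFactors = FALSE)
}

validate_seq_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "description", "sequence") %in% names(records)))
  if (any(!nzchar(records$id)) || any(grepl("[[:space:]]", records$id))) {
    stop("record ids must be non-empty and contain no whitespace",
         call. = FALSE)
  }
  if (any(!nzchar(records$sequence))) {
    stop("zero-length sequences are not allowed", call. = FALSE)
  }
  if (any(grepl("[^A-Za-z*]", records$sequence))) {
    stop("sequences may contain only alphabetic characters", call. = FALSE)
  }
  invisible(records)
}

split_header <- function(header) {
  header <- sub("^[>@]", "", header)
  id <- sub("[[:space:]].*$", "", header)
  desc <- sub("^[^[:space:]]*[[:space:]]*", "", header)
  list(id = id, description = desc)
}

#' Read sequence records from FASTA or FASTQ
#'
#' Returns one record per entry, in file order, as a data frame with
#' columns `id`, `description` and `sequence`. The id is the header token
#' up to the first whitespace; the remainder of the header is kept as the
#' description. Multi-line FASTA sequences are concatenated; FASTQ quality
#' strings are checked for length but discarded. Sequences are upper-cased
#' on ingest. FASTQ parsing is record-structure driven (4-line blocks), so
#' quality lines beginning with `@` are handled correctly.
#'
#' @param path Input file path.
#' @param format `"auto"` (default, via [detect_format()]), `"fasta"` or
#'   `"fastq"`.
#' @return A data frame with columns `id`, `description`, `sequence`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") format <- detect_format(path)
  lines <- readLines(path, warn = FALSE)
  if (format == "fasta") parse_fasta_lines(lines) else parse_fastq_lines(lines)
}

parse_fasta_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(new_seq_records())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[[1L]]) {
    stop("malformed FASTA: first non-blank line is not a '>' header",
         call. = FALSE)
  }
  grp <- cumsum(is_hdr)
  headers <- lines[is_hdr]
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste0,
                 character(1), collapse = "")
  # headers with no sequence lines are zero-length records
  full <- setNames(rep("", length(headers)), as.character(seq_along(headers)))
  full[names(seqs)] <- seqs
  hd <- split_header(headers)
  if (any(!nzchar(full))) {
    bad <- hd$id[!nzchar(full)][[1L]]
    stop("malformed record '", bad, "': zero-length sequence", call. = FALSE)
  }
  out <- new_seq_records(hd$id, hd$description, toupper(unname(full)))
  validate_seq_records(out)
  out
}

parse_fastq_lines <- function(lines) {
  # trailing blank lines are tolerated; internal structure is 4-line blocks
  while (length(lines) > 0L && !nzchar(trimws(lines[[length(lines)]]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) return(new_seq_records())
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: truncated final record (line count not a ",
         "multiple of 4)", call. = FALSE)
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (any(!startsWith(hdr, "@"))) {
    stop("malformed FASTQ: record header does not start with '@' at block ",
         which(!startsWith(hdr, "@"))[[1L]], call. = FALSE)
  }
  if (any(!startsWith(plus, "+"))) {
    stop("malformed FASTQ: separator line does not start with '+' at block ",
         which(!startsWith(plus, "+"))[[1L]], call. = FALSE)
  }
  hd <- split_header(hdr)
  bad <- nchar(seq) != nchar(qual)
  if (any(bad)) {
    stop("malformed record '", hd$id[bad][[1L]],
         "': sequence and quality lengths differ", call. = FALSE)
  }
  out <- new_seq_records(hd$id, hd$description, toupper(seq))
  validate_seq_records(out)
  out
}

#' Write sequence records as FASTA
#'
#' @param records Data frame with columns `id`, `description`, `sequence`.
#' @param path Output path. If `NULL`, the FASTA text is returned as a
#'   character string instead of written.
#' @param wrap Residues per sequence line; `0` writes each sequence on a
#'   single line. Default 70.
#' @return The path (invisibly), or the FASTA text when `path` is `NULL`.
#' @export
write_fasta <- function(records, path = NULL, wrap = 70L) {
  stopifnot(wrap >= 0L)
  validate_seq_records(records)
  if (nrow(records) == 0L) {
    txt <- ""
  } else {
    hdr <- ifelse(nzchar(records$description),
                  paste0(">", records$id, " ", records$description),
                  paste0(">", records$id))
    body <- if (wrap == 0L) {
      records$sequence
    } else {
      vapply(records$sequence, function(s) {
        starts <- seq(1L, nchar(s), by = wrap)
        paste(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))),
              collapse = "\n")
      }, character(1), USE.NAMES = FALSE)
    }
    txt <- paste0(paste(hdr, body, sep = "\n", collapse = "\n"), "\n")
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Read a 12-column tabular hit file
#'
#' Parses the standard tab-delimited local-alignment summary (the BLAST
#' "outfmt 6" dialect): qseqid, sseqid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore. Lines starting with `#`
#' are skipped; extra trailing columns are ignored. `s_start > s_end`
#' encodes a minus-strand subject match.
#'
#' @param path Path to the tab-delimited file.
#' @return A data frame with the 12 hit columns (see `HIT_COLUMNS`).
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L)) {
    stop("malformed hit-table line ", lineno[nf < 12L][[1L]],
         ": fewer than 12 tab-separated fields", call. = FALSE)
  }
  mat <- t(vapply(parts, function(p) p[1:12], character(12)))
  hits <- data.frame(query_id = mat[, 1], subject_id = mat[, 2],
                     stringsAsFactors = FALSE)
  numcols <- HIT_COLUMNS[3:12]
  for (k in seq_along(numcols)) {
    v <- suppressWarnings(as.numeric(mat[, k + 2L]))
    if (anyNA(v)) {
      stop("malformed hit-table line ", lineno[is.na(v)][[1L]],
           ": non-numeric value in field '", numcols[[k]], "'",
           call. = FALSE)
    }
    hits[[numcols[[k]]]] <- v
  }
  int_cols <- c("alignment_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end")
  for (cl in int_cols) hits[[cl]] <- as.integer(hits[[cl]])
  validate_hits(hits)
  hits
}

empty_hits <- function() {
  h <- data.frame(query_id = character(), subject_id = character(),
                  percent_identity = numeric(), alignment_length = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  evalue = numeric(), bit_score = numeric(),
                  stringsAsFactors = FALSE)
  h
}

validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits), all(HIT_COLUMNS %in% names(hits)))
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$q_start > hits$q_end)) {
    stop("invalid hit: q_start > q_end", call. = FALSE)
  }
  if (any(hits$evalue < 0)) stop("invalid hit: negative evalue", call. = FALSE)
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop("invalid hit: percent identity outside [0, 100]", call. = FALSE)
  }
  invisible(hits)
}

#' Write hits as a 12-column tab-delimited table
#'
#' Round-trips through [read_hit_table()] to printed precision: percent
#' identity with two decimals, E-values in scientific notation.
#'
#' @param hits Hit data frame (see [read_hit_table()] for the columns).
#' @param path Output path, or `NULL` to return the text.
#' @return The path (invisibly), or the text when `path` is `NULL`.
#' @export
write_hit_table <- function(hits, path = NULL) {
  validate_hits(hits)
  if (nrow(hits) == 0L) {
    txt <- ""
  } else {
    lines <- paste(hits$query_id, hits$subject_id,
                   sprintf("%.2f", hits$percent_identity),
                   hits$alignment_length, hits$mismatches, hits$gap_opens,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   format_evalue(hits$evalue),
                   sprintf("%.1f", hits$bit_score),
                   sep = "\t")
    txt <- paste0(paste(lines, collapse = "\n"), "\n")
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

format_evalue <- function(e) {
  out <- sprintf("%.2e", e)
  out[e == 0] <- "0.0"
  out
}
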