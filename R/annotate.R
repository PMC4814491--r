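#' Build a taxon map
#'
#' Associates each database/reference sequence id with a taxon label
#' (e.g. `"Mimiviridae"`, `"virophage"`, `"cellular"`) and designates the
#' target taxa — the labels that count as a confirmed detection when they
#' own a read's best hit.
#'
#' @param ids Character vector of sequence ids.
#' @param taxa Character vector of taxon labels, parallel to `ids`.
#' @param target_taxa Character vector of target taxon labels (non-empty).
#' @param query_ids Optional ids of the query set; when given, every query
#'   id must be present and must map to a target taxon.
#' @return A list of class `taxon_map` with `taxa` (named character
#'   vector) and `target_taxa`.
#' @export
taxon_map <- function(ids, taxa, target_taxa, query_ids = NULL) {
  stopifnot(length(ids) == length(taxa), length(target_taxa) > 0)
  if (anyDuplicated(ids)) stop("duplicated ids in taxon map", call. = FALSE)
  m <- stats::setNames(as.character(taxa), as.character(ids))
  if (!is.null(query_ids)) {
    missing <- setdiff(query_ids, ids)
    if (length(missing) > 0L) {
      stop("taxon map lacks query-set ids: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    off <- query_ids[!(m[query_ids] %in% target_taxa)]
    if (length(off) > 0L) {
      stop("query-set ids mapped to non-target taxa: ",
           paste(head(off, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(taxa = m, target_taxa = unique(as.character(target_taxa))),
            class = "taxon_map")
}

#' Read a taxon map from TSV
#'
#' Two or three tab-separated columns: sequence id, taxon label, and an
#' optional `is_target` flag (0/1). Without the flag column a taxon is a
#' target iff its sequence id is in `query_ids`.
#'
#' @param path Path to the TSV file (no header).
#' @param query_ids Query-set ids, used to derive targets when the flag
#'   column is absent, and to validate coverage when present.
#' @return A `taxon_map`.
#' @export
read_taxon_map <- function(path, query_ids = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxon map needs at least 2 columns", call. = FALSE)
  targets <- if (ncol(df) >= 3L) {
    unique(df[[2L]][df[[3L]] == 1])
  } else {
    if (is.null(query_ids)) {
      stop("taxon map has no is_target column and no query set was given",
           call. = FALSE)
    }
    unique(df[[2L]][df[[1L]] %in% query_ids])
  }
  taxon_map(df[[1L]], df[[2L]], targets, query_ids = query_ids)
}

#' Select candidate reads from first-pass hits
#'
#' Reads with at least one hit at or below the E-value cutoff, in order of
#' first appearance in the hit list.
#'
#' @param hits Hit data frame (reads vs the query set).
#' @param cutoff E-value threshold (default 1e-5).
#' @return Character vector of read ids.
#' @export
select_candidates <- function(hits, cutoff = 1e-5) {
  validate_hits(hits)
  unique(hits$query_id[hits$evalue <= cutoff])
}

#' Best hit of one read
#'
#' The hit with minimum E-value; ties broken by maximum bit score, then
#' lexicographically smallest subject id, making the rule total and the
#' result independent of input order.
#'
#' @param hits Non-empty hit data frame for a single read.
#' @return A one-row hit data frame.
#' @export
best_hit <- function(hits) {
  validate_hits(hits)
  if (nrow(hits) == 0L) stop("best_hit: empty hit list", call. = FALSE)
  if (length(unique(hits$query_id)) != 1L) {
    stop("best_hit expects hits of a single read", call. = FALSE)
  }
  o <- order(hits$evalue, -hits$bit_score,
             rank_lexico(hits$subject_id))
  hits[o[[1L]], , drop = FALSE]
}

# locale-independent lexicographic rank
rank_lexico <- function(x) {
  match(x, sort(unique(x), method = "radix"))
}

#' Classify candidate reads by the reciprocal best-hit test
#'
#' Implements the confirmation step: a candidate read (selected for
#' hitting the query set) is classified `positive` when its best hit
#' against the full reference database belongs to a target taxon,
#' `negative` when a non-target sequence owns the best hit, `ambiguous`
#' when target and non-target subjects tie the best hit exactly on
#' (E-value, bit score), and `unresolved` when it has no reference hits
#' at all (only reachable when the reference lacks the query set).
#'
#' @param step3_hits Hit data frame of candidate reads against the
#'   reference database, already filtered to the confirmation E-value
#'   cutoff.
#' @param taxa A [taxon_map()] covering every subject id in `step3_hits`.
#' @param candidates Character vector of candidate read ids (from
#'   [select_candidates()]).
#' @return A data frame with one row per candidate: `read_id`, `status`,
#'   `best_subject_id`, `best_evalue`, `best_bit_score`, `best_taxon`
#'   (evidence columns are `NA` for unresolved reads).
#' @export
classify_reads <- function(step3_hits, taxa, candidates) {
  stopifnot(inherits(taxa, "taxon_map"))
  validate_hits(step3_hits)
  stray <- setdiff(unique(step3_hits$query_id), candidates)
  if (length(stray) > 0L) {
    stop("reference hits name non-candidate reads: ",
         paste(head(stray, 5), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(step3_hits$subject_id), names(taxa$taxa))
  if (length(unknown) > 0L) {
    stop("taxon map lacks subject ids: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  empty_cls <- data.frame(read_id = character(), status = character(),
                          best_subject_id = character(),
                          best_evalue = numeric(), best_bit_score = numeric(),
                          best_taxon = character(), stringsAsFactors = FALSE)
  if (length(candidates) == 0L) return(empty_cls)
  rows <- lapply(candidates, function(rid) {
    h <- step3_hits[step3_hits$query_id == rid, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(data.frame(read_id = rid, status = "unresolved",
                        best_subject_id = NA_character_,
                        best_evalue = NA_real_, best_bit_score = NA_real_,
                        best_taxon = NA_character_,
                        stringsAsFactors = FALSE))
    }
    b <- best_hit(h)
    tie <- h[h$evalue == b$evalue & h$bit_score == b$bit_score, , drop = FALSE]
    tie_taxa <- unname(taxa$taxa[tie$subject_id])
    in_target <- tie_taxa %in% taxa$target_taxa
    status <- if (any(in_target) && any(!in_target)) {
      "ambiguous"
    } else if (unname(taxa$taxa[b$subject_id]) %in% taxa$target_taxa) {
      "positive"
    } else {
      "negative"
    }
    data.frame(read_id = rid, status = status,
               best_subject_id = b$subject_id, best_evalue = b$evalue,
               best_bit_score = b$bit_score,
               best_taxon = unname(taxa$taxa[b$subject_id]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally positive reads by taxon
#'
#' @param classifications Output of [classify_reads()].
#' @return A list with `per_taxon` (named integer vector of positive-read
#'   counts) and `total` (number of positives).
#' @export
tally_by_taxon <- function(classifications) {
  pos <- classifications[classifications$status == "positive", , drop = FALSE]
  tab <- table(pos$best_taxon)
  counts <- stats::setNames(as.integer(tab), names(tab))
  list(per_taxon = counts, total = sum(counts))
}
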