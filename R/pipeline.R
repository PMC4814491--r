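PIPELINE_STAGES <- c("clean", "search2", "search3", "classify", "report")

#' Pipeline configuration
#'
#' Bundles the inputs and parameters of a full three-step run: cleaning,
#' first-pass search of the reads against the query set, confirmation
#' search against the reference database, reciprocal best-hit
#' classification and report generation. All stages communicate through
#' files in `out_dir`, so any stage can be re-run independently and an
#' external aligner's tabular output can stand in for either search.
#'
#' @param reads Path to the input read file (FASTA or FASTQ).
#' @param query Path to the query set FASTA (nucleotide or protein).
#' @param reference Path to the reference FASTA; must contain the query
#'   set (checked through the taxon map) unless
#'   `allow_missing_query_in_reference`. `NULL` means use the query set
#'   itself as the reference.
#' @param taxa Path to the taxon map TSV (see [read_taxon_map()]).
#' @param out_dir Output directory.
#' @param cleaning A [cleaning_params()].
#' @param search2,search3 [search_params()] for the two searches; both
#'   default to an E-value cutoff of 1e-5, independently configurable.
#' @param external_step2,external_step3 Optional paths to pre-computed
#'   tabular hit files replacing the built-in searcher for that step.
#' @param metagenome_id Label recorded in the run summary; defaults to
#'   the read file name.
#' @param allow_missing_query_in_reference Allow a reference that lacks
#'   query sequences (makes the `unresolved` status reachable).
#' @param cpu_count CPU count recorded in the summary (results are
#'   independent of it).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, query, reference = NULL, taxa,
                            out_dir, cleaning = cleaning_params(),
                            search2 = search_params(),
                            search3 = search_params(),
                            external_step2 = NULL, external_step3 = NULL,
                            metagenome_id = basename(reads),
                            allow_missing_query_in_reference = FALSE,
                            cpu_count = 1L) {
  for (p in c(reads, query, reference, taxa, external_step2, external_step3)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  stopifnot(inherits(cleaning, "cleaning_params"),
            inherits(search2, "search_params"),
            inherits(search3, "search_params"))
  structure(list(reads = reads, query = query, reference = reference,
                 taxa = taxa, out_dir = out_dir, cleaning = cleaning,
                 search2 = search2, search3 = search3,
                 external_step2 = external_step2,
                 external_step3 = external_step3,
                 metagenome_id = metagenome_id,
                 allow_missing_query_in_reference =
                   isTRUE(allow_missing_query_in_reference),
                 cpu_count = as.integer(cpu_count)),
            class = "pipeline_config")
}

pipe_path <- function(config, name) file.path(config$out_dir, name)

run_stage <- function(config, stage, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] stage start", stage))
  res <- tryCatch(expr, error = function(e) {
    marker <- pipe_path(config, paste0("FAILED_", stage))
    writeLines(conditionMessage(e), marker)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] stage done in %.1f s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the detection pipeline
#'
#' Executes convert/clean, the first-pass search of reads against the
#' query set, the confirmation search against the reference, the
#' reciprocal best-hit classification and the report stage. Each stage
#' persists its output under `out_dir`, so re-running a subset of
#' `stages` on existing intermediates reproduces identical results.
#'
#' @param config A [pipeline_config()].
#' @param stages Stages to run, a contiguous subset of
#'   `c("clean", "search2", "search3", "classify", "report")`.
#' @return Named character vector of the output file paths, invisibly
#'   (from the report stage), or `NULL` when `"report"` is not among the
#'   requested stages.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"),
            all(stages %in% PIPELINE_STAGES))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()

  query <- read_sequences(config$query)
  taxa <- read_taxon_map(config$taxa, query_ids = query$id)

  if ("clean" %in% stages) {
    run_stage(config, "clean", {
      raw <- read_sequences(config$reads)
      cleaned <- clean_reads(raw, config$cleaning)
      write_fasta(cleaned$records, pipe_path(config, "clean.fasta"))
      write_cleaning_report(cleaned$report,
                            pipe_path(config, "cleaning_report.tsv"))
      message(sprintf("[clean] %d of %d reads retained",
                      cleaned$report$n_retained, cleaned$report$n_input))
    })
  }

  if ("search2" %in% stages) {
    run_stage(config, "search2", {
      reads <- read_sequences(pipe_path(config, "clean.fasta"))
      hits <- run_search(reads, query, config$search2,
                         external_hits = config$external_step2)
      write_hit_table(hits, pipe_path(config, "step2_hits.tsv"))
      message(sprintf("[search2] %d hits for %d reads", nrow(hits),
                      length(unique(hits$query_id))))
    })
  }

  if ("search3" %in% stages) {
    run_stage(config, "search3", {
      step2 <- read_hit_table(pipe_path(config, "step2_hits.tsv"))
      candidates <- select_candidates(step2, config$search2$evalue_cutoff)
      writeLines(candidates, pipe_path(config, "candidates.txt"))
      reads <- read_sequences(pipe_path(config, "clean.fasta"))
      cand_reads <- reads[reads$id %in% candidates, , drop = FALSE]
      if (is.null(config$external_step3)) {
        reference <- if (is.null(config$reference)) query else
          read_sequences(config$reference)
        check_reference_coverage(reference, query, config)
        hits <- run_search(cand_reads, reference, config$search3)
      } else {
        hits <- run_search(cand_reads, params = config$search3,
                           external_hits = config$external_step3)
      }
      write_hit_table(hits, pipe_path(config, "step3_hits.tsv"))
      message(sprintf("[search3] %d reference hits for %d candidates",
                      nrow(hits), length(candidates)))
    })
  }

  if ("classify" %in% stages) {
    run_stage(config, "classify", {
      candidates <- read_candidates(pipe_path(config, "candidates.txt"))
      step3 <- read_hit_table(pipe_path(config, "step3_hits.tsv"))
      cls <- classify_reads(step3, taxa, candidates)
      write.table(cls, pipe_path(config, "classifications.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      message(sprintf("[classify] %d positive of %d candidates",
                      sum(cls$status == "positive"), nrow(cls)))
    })
  }

  if ("report" %in% stages) {
    return(run_stage(config, "report", {
      reads <- read_sequences(pipe_path(config, "clean.fasta"))
      step2 <- read_hit_table(pipe_path(config, "step2_hits.tsv"))
      step3 <- read_hit_table(pipe_path(config, "step3_hits.tsv"))
      candidates <- read_candidates(pipe_path(config, "candidates.txt"))
      cls <- utils::read.delim(pipe_path(config, "classifications.tsv"),
                               stringsAsFactors = FALSE,
                               colClasses = c(read_id = "character",
                                              best_subject_id = "character"))
      summary <- summarize_run(
        metagenome_id = config$metagenome_id,
        n_processed = nrow(reads), candidates = candidates,
        classifications = cls,
        duration = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
        cpu_count = config$cpu_count,
        parameters = config_snapshot(config))
      invisible(write_outputs(config$out_dir, step2, step3, cls, reads,
                              summary))
    }))
  }
  invisible(NULL)
}

read_candidates <- function(path) {
  if (!file.exists(path)) stop("missing candidates file: ", path,
                               call. = FALSE)
  cand <- readLines(path, warn = FALSE)
  cand[nzchar(cand)]
}

check_reference_coverage <- function(reference, query, config) {
  missing <- setdiff(query$id, reference$id)
  if (length(missing) > 0L && !config$allow_missing_query_in_reference) {
    stop("reference database lacks ", length(missing), " query sequences ",
         "(e.g. ", paste(head(missing, 3), collapse = ", "), "); pass ",
         "allow_missing_query_in_reference = TRUE to proceed anyway",
         call. = FALSE)
  }
  invisible(TRUE)
}

config_snapshot <- function(config) {
  list(reads = config$reads, query = config$query,
       reference = config$reference, taxa = config$taxa,
       cleaning = unclass(config$cleaning),
       search2 = search_snapshot(config$search2),
       search3 = search_snapshot(config$search3),
       external_step2 = config$external_step2,
       external_step3 = config$external_step3)
}

search_snapshot <- function(sp) {
  list(mode = sp$mode, k = sp$k, x_drop = sp$x_drop,
       evalue_cutoff = sp$evalue_cutoff, lambda = sp$lambda, K = sp$K,
       scoring_kind = if (is.null(sp$scoring)) "default" else sp$scoring$kind)
}
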