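#' Parameters for a synthetic metagenome
#'
#' Defines a synthetic read set with known truth: background reads drawn
#' base-by-base at a given GC content, plus reads planted as substrings of
#' supplied source sequences (the "virus genomes"), optionally mutated,
#' N-masked and duplicated. Planted reads come from the forward strand
#' with probability 0.5 and from the reverse complement otherwise, so
#' minus-strand hit encoding is exercised.
#'
#' Defaults describe a small but realistic desk-scale benchmark: 10,000
#' background reads and 200 planted reads of 100 nt, 1% substitutions,
#' 0.5% N positions, and 5% of reads emitted twice.
#'
#' @param n_background Number of background reads. Default 10000.
#' @param n_planted Number of planted (source-derived) reads. Default 200.
#' @param read_length Single length or `c(min, max)` range in
#'   nucleotides. Default 100.
#' @param sources Source sequence data frame (required when
#'   `n_planted > 0`); every source must be at least as long as the
#'   largest read length.
#' @param substitution_rate Per-base substitution probability for planted
#'   reads. Default 0.01.
#' @param ambiguity_rate Per-base probability of replacement by `N`.
#'   Default 0.005.
#' @param duplication_fraction Fraction of reads re-emitted as an exact
#'   copy under a fresh id. Default 0.05.
#' @param background_gc GC content of background reads. Default 0.5.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_background = 10000L, n_planted = 200L,
                              read_length = 100L, sources = NULL,
                              substitution_rate = 0.01,
                              ambiguity_rate = 0.005,
                              duplication_fraction = 0.05,
                              background_gc = 0.5, seed = 1L) {
  rates <- c(substitution_rate, ambiguity_rate, duplication_fraction,
             background_gc)
  stopifnot(n_background >= 0, n_planted >= 0,
            all(rates >= 0), all(rates <= 1),
            length(read_length) %in% c(1L, 2L), all(read_length >= 1))
  if (n_planted > 0) {
    if (is.null(sources) || nrow(sources) == 0L) {
      stop("planted reads require non-empty sources", call. = FALSE)
    }
    if (max(read_length) > min(nchar(sources$sequence))) {
      stop("read_length exceeds the shortest source sequence", call. = FALSE)
    }
  }
  structure(list(n_background = as.integer(n_background),
                 n_planted = as.integer(n_planted),
                 read_length = as.integer(read_length),
                 sources = sources,
                 substitution_rate = substitution_rate,
                 ambiguity_rate = ambiguity_rate,
                 duplication_fraction = duplication_fraction,
                 background_gc = background_gc,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Mutate a nucleotide sequence
#'
#' Each position is independently substituted (by a uniformly chosen
#' different base) with probability `substitution_rate`, then
#' independently replaced by `N` with probability `ambiguity_rate`.
#' Length is preserved. Uses the current RNG state.
#'
#' @param sequence Nucleotide string.
#' @param substitution_rate,ambiguity_rate Per-base probabilities.
#' @return A list with `sequence`, `n_substitutions`, `n_ambiguities`.
#' @export
mutate_sequence <- function(sequence, substitution_rate = 0,
                            ambiguity_rate = 0) {
  bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(bases)
  sub_at <- stats::runif(L) < substitution_rate
  if (any(sub_at)) {
    alt <- vapply(bases[sub_at], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    bases[sub_at] <- alt
  }
  amb_at <- stats::runif(L) < ambiguity_rate
  bases[amb_at] <- "N"
  list(sequence = paste(bases, collapse = ""),
       n_substitutions = sum(sub_at & !amb_at),
       n_ambiguities = sum(amb_at))
}

random_dna <- function(n, length, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Generate a synthetic metagenome with truth labels
#'
#' @param params A [simulation_params()] object.
#' @return A list with `records` (read data frame, deterministically
#'   shuffled) and `truth`, a data frame with one row per emitted read:
#'   `read_id`, `origin` (background/planted), `source_id`,
#'   `source_start`, `strand`, `n_substitutions`, `n_ambiguities`,
#'   `is_duplicate`.
#' @export
generate_metagenome <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  draw_len <- function(n) {
    if (length(params$read_length) == 1L) {
      rep(params$read_length, n)
    } else {
      sample(params$read_length[[1L]]:params$read_length[[2L]], n,
             replace = TRUE)
    }
  }

  recs <- list()
  truth <- list()
  if (params$n_background > 0L) {
    len <- draw_len(params$n_background)
    seqs <- vapply(len, function(L) {
      random_dna(1L, L, params$background_gc)
    }, character(1))
    ids <- sprintf("bg_%05d", seq_len(params$n_background))
    recs[[1L]] <- new_seq_records(ids, "", seqs)
    truth[[1L]] <- data.frame(read_id = ids, origin = "background",
                              source_id = NA_character_,
                              source_start = NA_integer_,
                              strand = NA_character_,
                              n_substitutions = 0L, n_ambiguities = 0L,
                              is_duplicate = FALSE, stringsAsFactors = FALSE)
  }
  if (params$n_planted > 0L) {
    src <- params$sources
    len <- draw_len(params$n_planted)
    pick <- sample.int(nrow(src), params$n_planted, replace = TRUE)
    ids <- sprintf("pl_%05d", seq_len(params$n_planted))
    seqs <- character(params$n_planted)
    starts <- integer(params$n_planted)
    strands <- character(params$n_planted)
    nsub <- integer(params$n_planted)
    namb <- integer(params$n_planted)
    for (i in seq_len(params$n_planted)) {
      Ls <- nchar(src$sequence[[pick[[i]]]])
      starts[[i]] <- sample.int(Ls - len[[i]] + 1L, 1L)
      frag <- substr(src$sequence[[pick[[i]]]], starts[[i]],
                     starts[[i]] + len[[i]] - 1L)
      strands[[i]] <- if (stats::runif(1) < 0.5) "+" else "-"
      if (strands[[i]] == "-") frag <- reverse_complement(frag)
      mut <- mutate_sequence(frag, params$substitution_rate,
                             params$ambiguity_rate)
      seqs[[i]] <- mut$sequence
      nsub[[i]] <- mut$n_substitutions
      namb[[i]] <- mut$n_ambiguities
    }
    recs[[length(recs) + 1L]] <- new_seq_records(ids, "", seqs)
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = ids, origin = "planted", source_id = src$id[pick],
      source_start = starts, strand = strands, n_substitutions = nsub,
      n_ambiguities = namb, is_duplicate = FALSE, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  truth <- do.call(rbind, truth)
  if (is.null(records)) {
    return(list(records = new_seq_records(),
                truth = data.frame(read_id = character(), origin = character(),
                                   source_id = character(),
                                   source_start = integer(),
                                   strand = character(),
                                   n_substitutions = integer(),
                                   n_ambiguities = integer(),
                                   is_duplicate = logical(),
                                   stringsAsFactors = FALSE)))
  }

  n <- nrow(records)
  dup_at <- which(stats::runif(n) < params$duplication_fraction)
  if (length(dup_at) > 0L) {
    dup_recs <- records[dup_at, , drop = FALSE]
    dup_truth <- truth[dup_at, , drop = FALSE]
    dup_recs$id <- paste0(dup_recs$id, "_dup")
    dup_truth$read_id <- dup_recs$id
    dup_truth$is_duplicate <- TRUE
    records <- rbind(records, dup_recs)
    truth <- rbind(truth, dup_truth)
  }
  perm <- sample.int(nrow(records))
  records <- records[perm, , drop = FALSE]
  truth <- truth[perm, , drop = FALSE]
  rownames(records) <- rownames(truth) <- NULL
  list(records = records, truth = truth)
}

#' Generate random source "genomes" for simulations
#'
#' Convenience generator for labelled source sequences to use as a query
#' set in tests and examples.
#'
#' @param n Number of sources.
#' @param length Length of each source in nucleotides.
#' @param gc GC content.
#' @param prefix Id prefix (default `"virus"`).
#' @param seed Integer seed.
#' @return A sequence data frame.
#' @export
random_sources <- function(n = 3L, length = 10000L, gc = 0.45,
                           prefix = "virus", seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  new_seq_records(sprintf("%s_%02d", prefix, seq_len(n)), "",
                  random_dna(n, length, gc))
}
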