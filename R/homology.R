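NT_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

#' Scoring scheme for local alignment
#'
#' Defines the substitution scores, gap penalties and background letter
#' frequencies used by the aligner and by the E-value statistics. A gap of
#' length L costs `gap_open + L * gap_extend` (both non-positive).
#'
#' Nucleotide schemes score identical ACGT letters with `match` and every
#' other pair — including any pair involving an ambiguity code — with
#' `mismatch`. Protein schemes use a named standard substitution matrix
#' (BLOSUM62 by default, via Biostrings). Background frequencies default
#' to uniform over the unambiguous alphabet; the expected per-column score
#' under them must be negative for the E-value theory to apply.
#'
#' @param kind `"nucleotide"` or `"protein"`.
#' @param match,mismatch Nucleotide match reward / mismatch penalty.
#'   Defaults +1 / -2.
#' @param matrix Protein substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties (non-positive). Defaults:
#'   nucleotide -5 / -2 (affine, as in standard nucleotide aligners: a
#'   zero opening cost lets single-gap columns cost no more than a
#'   mismatch, which invalidates the ungapped E-value statistics),
#'   protein -11 / -1.
#' @param background_freqs Named per-letter probabilities summing to 1, or
#'   `NULL` for uniform over ACGT (nucleotide) or the 20 amino acids.
#' @return A list of class `scoring_scheme` with the substitution matrix,
#'   its alphabet and the parameters above.
#' @export
scoring_scheme <- function(kind = c("nucleotide", "protein"),
                           match = 1L, mismatch = -2L,
                           matrix = "BLOSUM62",
                           gap_open = NULL, gap_extend = NULL,
                           background_freqs = NULL) {
  kind <- match.arg(kind)
  if (kind == "nucleotide") {
    stopifnot(match > 0, mismatch <= 0)
    letters <- c("A", "C", "G", "T", NT_AMBIG)
    mat <- base::matrix(as.numeric(mismatch), length(letters), length(letters),
                        dimnames = list(letters, letters))
    diag(mat)[1:4] <- match
    mat["N", "N"] <- mismatch  # ambiguity never rewarded, even N vs N
    if (is.null(gap_open)) gap_open <- -5
    if (is.null(gap_extend)) gap_extend <- -2
    if (is.null(background_freqs)) {
      background_freqs <- setNames(rep(0.25, 4), c("A", "C", "G", "T"))
    }
  } else {
    mat_name <- matrix
    e <- new.env()
    utils::data(list = mat_name, package = "Biostrings", envir = e)
    mat <- get(mat_name, envir = e)
    mat <- mat[rownames(mat) != "*", colnames(mat) != "*", drop = FALSE]
    storage.mode(mat) <- "double"
    if (is.null(gap_open)) gap_open <- -11
    if (is.null(gap_extend)) gap_extend <- -1
    if (is.null(background_freqs)) {
      background_freqs <- setNames(rep(1 / 20, 20), AA20)
    }
  }
  stopifnot(gap_open <= 0, gap_extend <= 0,
            abs(sum(background_freqs) - 1) < 1e-8,
            all(names(background_freqs) %in% rownames(mat)))
  structure(list(kind = kind, matrix = mat,
                 alphabet = rownames(mat),
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend),
                 background_freqs = background_freqs),
            class = "scoring_scheme")
}

#' Search parameters for the built-in homology searcher
#'
#' @param mode `"nucleotide"` (BLASTn-like), `"translated"` (tBLASTn-like;
#'   reads searched in six translated frames against a protein database),
#'   or `"auto"` (decide from database composition: at least 90% ACGTN
#'   residues means nucleotide).
#' @param k Exact seed length in residues; defaults to 11 for nucleotide
#'   and 3 for translated mode.
#' @param x_drop Non-negative score drop allowed around a seed before the
#'   extension window is cut off. Default 20.
#' @param evalue_cutoff Maximum reported E-value. Default 1e-5.
#' @param scoring A [scoring_scheme()], or `NULL` for the mode's default.
#' @param lambda,K Karlin-Altschul parameters. `NULL` (the default for
#'   both) computes them from the scoring scheme via [karlin_lambda()]
#'   and [karlin_K()]. The built-in searcher's E-values remain
#'   approximate (ungapped statistics, raw `m * n` search space without
#'   edge corrections) and are used for thresholding and ranking, not as
#'   calibrated probabilities.
#' @return A list of class `search_params`.
#' @export
search_params <- function(mode = c("auto", "nucleotide", "translated"),
                          k = NULL, x_drop = 20, evalue_cutoff = 1e-5,
                          scoring = NULL, lambda = NULL, K = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.null(k) || k >= 1, x_drop >= 0, evalue_cutoff > 0,
            is.null(K) || K > 0, is.null(lambda) || lambda > 0)
  structure(list(mode = mode, k = k, x_drop = x_drop,
                 evalue_cutoff = evalue_cutoff, scoring = scoring,
                 lambda = lambda, K = K),
            class = "search_params")
}

#' Karlin-Altschul lambda for a scoring scheme
#'
#' Solves for the unique positive root of
#' \eqn{\sum_{i,j} p_i p_j e^{\lambda s_{ij}} = 1}
#' over the letters with positive background frequency. Requires a
#' negative expected per-column score and at least one positive score.
#'
#' @param scoring A [scoring_scheme()].
#' @param tol Residual tolerance for the root (default 1e-12).
#' @return The positive real `lambda`.
#' @export
#' @examples
#' # +1/-1 uniform nucleotide scheme has the closed form lambda = ln 3
#' s <- scoring_scheme("nucleotide", match = 1, mismatch = -1)
#' karlin_lambda(s)  # 1.0986...
karlin_lambda <- function(scoring, tol = 1e-12) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  p <- scoring$background_freqs
  letters <- names(p)
  S <- scoring$matrix[letters, letters, drop = FALSE]
  pp <- outer(p, p)
  expected <- sum(pp * S)
  if (expected >= 0 || !any(S > 0)) {
    stop("no valid lambda: the scoring scheme must have negative expected ",
         "score and at least one positive score", call. = FALSE)
  }
  f <- function(lam) sum(pp * exp(lam * S)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lam <- stats::uniroot(f, c(1e-12, hi), tol = tol)$root
  if (abs(f(lam)) > 1e-9) {
    stop("lambda root-finding did not converge to residual < 1e-9",
         call. = FALSE)
  }
  lam
}

#' Karlin-Altschul K for an integer-valued scoring scheme
#'
#' Computes the K parameter of the ungapped local-alignment score
#' statistics by the standard convolution series: with score-step
#' distribution \eqn{p_s} (induced by the background frequencies and the
#' substitution matrix, integer scores), lattice spacing d (the gcd of
#' the support) and relative entropy
#' \eqn{H = \lambda \sum_s s\, p_s e^{\lambda s}},
#' \deqn{K = d\,\lambda\, e^{-2\sigma} / (H (1 - e^{-\lambda d})),}
#' where \eqn{\sigma = \sum_{j \ge 1} j^{-1} (\sum_{i<0} P_j(i) e^{\lambda i}
#' + \sum_{i \ge 0} P_j(i))} and \eqn{P_j} is the j-step convolution of
#' the score distribution. The series terms decay geometrically for any
#' valid (negative-drift) scheme; iteration stops at a residual of 1e-12.
#'
#' @param scoring A [scoring_scheme()] with integer scores.
#' @param lambda The scheme's lambda; computed via [karlin_lambda()] when
#'   omitted.
#' @param max_iter Maximum series terms (default 2000).
#' @return The positive real K.
#' @export
karlin_K <- function(scoring, lambda = karlin_lambda(scoring),
                     max_iter = 2000L) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  p <- scoring$background_freqs
  letters <- names(p)
  S <- scoring$matrix[letters, letters, drop = FALSE]
  if (any(S != round(S))) {
    stop("karlin_K requires integer-valued scores", call. = FALSE)
  }
  pp <- outer(p, p)
  lo <- as.integer(min(S))
  hi <- as.integer(max(S))
  step <- numeric(hi - lo + 1L)
  for (s in lo:hi) step[s - lo + 1L] <- sum(pp[S == s])
  support <- (lo:hi)[step > 0]
  gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)
  d <- Reduce(gcd2, abs(support[support != 0L]))
  H <- lambda * sum(pp * S * exp(lambda * S))

  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(b)) {
      if (b[[i]] == 0) next
      ii <- i:(i + length(a) - 1L)
      out[ii] <- out[ii] + a * b[[i]]
    }
    out
  }
  sigma <- 0
  cur <- step
  cur_lo <- lo
  for (j in seq_len(max_iter)) {
    vals <- seq(cur_lo, by = 1L, length.out = length(cur))
    neg <- vals < 0
    term <- sum(cur[neg] * exp(lambda * vals[neg])) + sum(cur[!neg])
    sigma <- sigma + term / j
    if (term / j < 1e-12) break
    cur <- conv(cur, step)
    cur_lo <- cur_lo + lo
  }
  d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
}

#' Karlin-Altschul E-value and bit score
#'
#' `evalue()` returns the expected number of chance alignments with score
#' at least `S` in a search space of `m * n` residues:
#' \eqn{E = K m n e^{-\lambda S}}. `bit_score()` is the companion
#' normalized score \eqn{(\lambda S - \ln K)/\ln 2}.
#'
#' @param S Raw alignment score (vectorized).
#' @param m Total query residues.
#' @param n Total database residues.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Numeric vector of E-values (or bit scores).
#' @export
evalue <- function(S, m, n, lambda, K) {
  stopifnot(m >= 1, n >= 1, lambda > 0, K > 0)
  K * m * n * exp(-lambda * S)
}

#' @rdname evalue
#' @export
bit_score <- function(S, lambda, K) {
  (lambda * S - log(K)) / log(2)
}

#' Optimal local alignment (Smith-Waterman / Gotoh)
#'
#' Computes a maximal-scoring local alignment with affine gaps. When no
#' letter pair scores positively the result has score 0 and an empty
#' alignment. Ties among maximal alignments are broken deterministically:
#' smallest query start, then smallest subject start.
#'
#' @param a,b Query and subject residue strings (non-empty).
#' @param scoring A [scoring_scheme()] whose alphabet covers both strings.
#' @return A list of class `local_alignment`: `score`, 1-based inclusive
#'   `q_start`, `q_end`, `s_start`, `s_end`, and the gapped
#'   `aligned_query` / `aligned_subject` strings.
#' @export
smith_waterman <- function(a, b, scoring = scoring_scheme("nucleotide")) {
  stopifnot(inherits(scoring, "scoring_scheme"), nzchar(a), nzchar(b))
  res <- sw_align_cpp(toupper(a), toupper(b), scoring$matrix,
                      scoring$alphabet, scoring$gap_open, scoring$gap_extend)
  structure(res, class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local alignment: score %g, query %s..%s, subject %s..%s\n",
              x$score, x$q_start, x$q_end, x$s_start, x$s_end))
  if (nzchar(x$aligned_query)) {
    cat(" ", x$aligned_query, "\n ", x$aligned_subject, "\n", sep = "")
  }
  invisible(x)
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of nucleotide sequences (IUPAC letters).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six frames under the standard
#' genetic code: +1, +2, +3 read from the forward strand, -1, -2, -3 from
#' the reverse complement. Stop codons are rendered `*`; codons containing
#' ambiguity codes that cannot be resolved translate to `X`; trailing
#' partial codons are dropped. Peptide position `p` of frame `f` maps back
#' to read nucleotides via [frame_to_nt()].
#'
#' @param nt Nucleotide string of length at least 3.
#' @return A data frame with columns `frame` (+1..+3, -1..-3) and
#'   `peptide`.
#' @export
translate_frames <- function(nt) {
  nt <- toupper(nt)
  L <- nchar(nt)
  if (L < 3L) stop("translate_frames: sequence shorter than one codon",
                   call. = FALSE)
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  pep <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(Biostrings::subseq(s, off + 1L, off + n),
                                       if.fuzzy.codon = "solve",
                                       no.init.codon = TRUE))
  }
  data.frame(frame = c(1L, 2L, 3L, -1L, -2L, -3L),
             peptide = c(pep(fwd, 0L), pep(fwd, 1L), pep(fwd, 2L),
                         pep(rev, 0L), pep(rev, 1L), pep(rev, 2L)),
             stringsAsFactors = FALSE)
}

#' Map a peptide interval in a translation frame to read coordinates
#'
#' @param frame Frame label in +1..+3, -1..-3.
#' @param p_start,p_end 1-based peptide positions within the frame's
#'   translation.
#' @param read_length Read length in nucleotides.
#' @return `c(nt_start, nt_end)` on the forward strand of the read
#'   (`nt_start <= nt_end`).
#' @export
frame_to_nt <- function(frame, p_start, p_end, read_length) {
  off <- abs(frame) - 1L
  a <- off + 3L * (p_start - 1L) + 1L
  b <- off + 3L * (p_end - 1L) + 3L
  if (frame > 0) c(a, b) else c(read_length - b + 1L, read_length - a + 1L)
}

alignment_stats <- function(aq, as_) {
  qs <- strsplit(aq, "", fixed = TRUE)[[1]]
  ss <- strsplit(as_, "", fixed = TRUE)[[1]]
  len <- length(qs)
  gap <- qs == "-" | ss == "-"
  ident <- sum(!gap & qs == ss)
  runs <- function(g) sum(g & !c(FALSE, g[-length(g)]))
  list(alignment_length = len,
       identities = ident,
       mismatches = sum(!gap & qs != ss),
       gap_opens = runs(qs == "-") + runs(ss == "-"))
}

resolve_mode <- function(mode, database) {
  if (mode != "auto") return(mode)
  res <- paste(database$sequence, collapse = "")
  frac <- mean(strsplit(res, "", fixed = TRUE)[[1]] %in%
                 c("A", "C", "G", "T", "N"))
  if (frac >= 0.9) "nucleotide" else "translated"
}

resolve_params <- function(params, mode) {
  if (is.null(params$scoring)) {
    params$scoring <- scoring_scheme(
      if (mode == "translated") "protein" else "nucleotide")
  }
  if (is.null(params$k)) params$k <- if (mode == "translated") 3L else 11L
  if (is.null(params$lambda)) params$lambda <- karlin_lambda(params$scoring)
  if (is.null(params$K)) {
    params$K <- karlin_K(params$scoring, params$lambda)
  }
  params
}

kmer_index <- function(seqs, k) {
  lens <- nchar(seqs)
  nk <- pmax(lens - k + 1L, 0L)
  if (sum(nk) == 0L) return(NULL)
  seq_i <- rep(seq_along(seqs), nk)
  pos <- sequence(nk)
  kmer <- substring(seqs[seq_i], pos, pos + k - 1L)
  list(seq = seq_i, pos = pos, index = split(seq_along(kmer), kmer))
}

# one hashed lookup for every k-mer of every read at once; returns a seed
# table (read, qpos, subject-sequence, subject position)
match_seeds <- function(read_seqs, k, idx) {
  lens <- nchar(read_seqs)
  nk <- pmax(lens - k + 1L, 0L)
  if (sum(nk) == 0L) return(NULL)
  read_i <- rep(seq_along(read_seqs), nk)
  qpos <- sequence(nk)
  kmer <- substring(read_seqs[read_i], qpos, qpos + k - 1L)
  gid <- match(kmer, names(idx$index))
  has <- !is.na(gid)
  if (!any(has)) return(NULL)
  ents <- idx$index[gid[has]]
  nent <- lengths(ents)
  rows <- unlist(ents, use.names = FALSE)
  data.frame(read = rep(read_i[has], nent), qpos = rep(qpos[has], nent),
             seq = idx$seq[rows], spos = idx$pos[rows])
}

#' Seed-and-extend homology search
#'
#' The built-in reference searcher behind the pipeline's BLAST-like steps.
#' For each read, exact k-mer seed matches against the database are
#' located (on both strands in nucleotide mode; on stop-split translated
#' frame segments in translated mode) and each seeded read/subject pair is
#' extended by an optimal Gotoh local alignment restricted to a window
#' around the seed diagonals (the window extends one read length plus
#' `x_drop` positions beyond the outermost seeds, so an alignment passing
#' through a seed is recovered in full). A reported alignment must be
#' anchored on a seed — contain at least one exact k-mer match — as in
#' any seed-and-extend aligner; when the window optimum is unanchored,
#' each seed is re-extended on a narrow band around its own diagonal.
#' Surviving alignments are reported as hits with approximate
#' Karlin-Altschul E-values; hits above `evalue_cutoff` are dropped.
#'
#' Output is deterministic: read input order, then ascending E-value, then
#' subject id. Minus-strand nucleotide matches are encoded
#' `s_start > s_end`, as in standard tabular alignment output.
#'
#' @param reads Read data frame (from [read_sequences()]).
#' @param database Database data frame of sequences to search against.
#' @param params A [search_params()].
#' @return A hit data frame in the 12-column tabular dialect.
#' @export
seeded_search <- function(reads, database, params = search_params()) {
  stopifnot(inherits(params, "search_params"))
  if (nrow(database) == 0L) stop("empty database", call. = FALSE)
  validate_seq_records(database)
  if (nrow(reads) > 0L) validate_seq_records(reads)
  mode <- resolve_mode(params$mode, database)
  params <- resolve_params(params, mode)
  k <- as.integer(params$k)
  if (all(nchar(database$sequence) < k)) {
    stop("seed length k = ", k, " exceeds every database sequence length",
         call. = FALSE)
  }
  if (mode == "nucleotide") {
    hits <- search_nucleotide(reads, database, params, k)
  } else {
    hits <- search_translated(reads, database, params, k)
  }
  order_hits(hits, reads$id)
}

order_hits <- function(hits, read_order) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(match(hits$query_id, read_order), hits$evalue, hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

make_hit <- function(query_id, subject_id, aln, s_start, s_end, m, n, params) {
  st <- alignment_stats(aln$aligned_query, aln$aligned_subject)
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = 100 * st$identities / st$alignment_length,
             alignment_length = st$alignment_length,
             mismatches = st$mismatches, gap_opens = st$gap_opens,
             q_start = aln$q_start, q_end = aln$q_end,
             s_start = as.integer(s_start), s_end = as.integer(s_end),
             evalue = evalue(aln$score, m, n, params$lambda, params$K),
             bit_score = bit_score(aln$score, params$lambda, params$K),
             score = aln$score,
             stringsAsFactors = FALSE)
}

search_nucleotide <- function(reads, database, params, k) {
  db_seqs <- toupper(database$sequence)
  n_db <- sum(nchar(db_seqs))
  # index both strands; strand-local coordinates are mapped back later
  strand_of <- rep(c("+", "-"), each = nrow(database))
  subj_of <- rep(seq_len(nrow(database)), 2L)
  strand_seqs <- c(db_seqs, reverse_complement(db_seqs))
  idx <- kmer_index(strand_seqs, k)
  if (is.null(idx)) stop("no indexable database sequence", call. = FALSE)
  read_seqs <- toupper(reads$sequence)
  seeds <- match_seeds(read_seqs, k, idx)
  if (is.null(seeds)) return(empty_hits())
  seeds$diag <- seeds$spos - seeds$qpos

  # one extension window per seeded (read, subject, strand) pair, spanning
  # the seed diagonals plus one read length and the x-drop allowance
  groups <- split(seq_len(nrow(seeds)),
                  list(read = seeds$read, seq = seeds$seq), drop = TRUE)
  ng <- length(groups)
  g_read <- vapply(groups, function(g) seeds$read[[g[[1L]]]], integer(1))
  g_seq <- vapply(groups, function(g) seeds$seq[[g[[1L]]]], integer(1))
  g_len <- nchar(read_seqs)[g_read]
  g_pad <- g_len + as.integer(ceiling(params$x_drop))
  g_mind <- vapply(groups, function(g) min(seeds$diag[g]), integer(1))
  g_maxd <- vapply(groups, function(g) max(seeds$diag[g]), integer(1))
  g_slen <- nchar(strand_seqs)[g_seq]
  g_lo <- pmax(1L, g_mind + 1L - g_pad)
  g_hi <- pmin(g_slen, g_maxd + g_len + g_pad)

  # batched score-only pass; traceback only for windows passing the cutoff
  windows <- substr(strand_seqs[g_seq], g_lo, g_hi)
  scores <- sw_score_batch(read_seqs[g_read], windows,
                           params$scoring$matrix, params$scoring$alphabet,
                           params$scoring$gap_open, params$scoring$gap_extend)
  ev <- evalue(scores, g_len, n_db, params$lambda, params$K)
  hit_rows <- list()
  for (gi in which(scores > 0 & ev <= params$evalue_cutoff)) {
    r <- g_read[[gi]]
    si <- g_seq[[gi]]
    L <- g_len[[gi]]
    Ls <- g_slen[[gi]]
    grp <- groups[[gi]]
    aln <- sw_align_cpp(read_seqs[[r]], windows[[gi]],
                        params$scoring$matrix, params$scoring$alphabet,
                        params$scoring$gap_open, params$scoring$gap_extend)
    s1 <- g_lo[[gi]] + aln$s_start - 1L
    s2 <- g_lo[[gi]] + aln$s_end - 1L
    if (!anchored_on_seed(aln$q_start, aln$q_end, s1, s2,
                          seeds$qpos[grp], seeds$spos[grp], k)) {
      # the window optimum is not seed-anchored: re-extend each seed on a
      # narrow diagonal band, as a true x-drop extension would
      aln <- anchored_fallback(read_seqs[[r]], strand_seqs[[si]],
                               seeds$qpos[grp], seeds$spos[grp], k, params)
      if (is.null(aln)) next
      if (evalue(aln$score, L, n_db, params$lambda, params$K) >
            params$evalue_cutoff) next
      s1 <- aln$s_start
      s2 <- aln$s_end
    }
    if (strand_of[[si]] == "-") {
      s1 <- Ls - s1 + 1L   # back to forward-strand coordinates;
      s2 <- Ls - s2 + 1L   # s1 > s2 now encodes the minus strand
    }
    hit_rows[[length(hit_rows) + 1L]] <-
      make_hit(reads$id[[r]], database$id[[subj_of[[si]]]], aln, s1, s2,
               m = L, n = n_db, params = params)
  }
  finish_hits(hit_rows)
}

anchored_on_seed <- function(q1, q2, s1, s2, qpos, spos, k) {
  any(qpos >= q1 & qpos + k - 1L <= q2 & spos >= s1 & spos + k - 1L <= s2)
}

# best seed-containing alignment: each seed is re-extended on a narrow
# window around its own diagonal
anchored_fallback <- function(read_seq, sseq, qpos, spos, k, params) {
  L <- nchar(read_seq)
  Ls <- nchar(sseq)
  pad <- as.integer(ceiling(params$x_drop)) + k
  best <- NULL
  diags <- unique(spos - qpos)
  for (d in diags) {
    on_d <- (spos - qpos) == d
    lo <- max(1L, d + 1L - pad)
    hi <- min(Ls, d + L + pad)
    aln <- sw_align_cpp(read_seq, substr(sseq, lo, hi),
                        params$scoring$matrix, params$scoring$alphabet,
                        params$scoring$gap_open, params$scoring$gap_extend)
    if (aln$score <= 0) next
    s1 <- lo + aln$s_start - 1L
    s2 <- lo + aln$s_end - 1L
    if (!anchored_on_seed(aln$q_start, aln$q_end, s1, s2,
                          qpos[on_d], spos[on_d], k)) next
    if (is.null(best) || aln$score > best$score) {
      aln$s_start <- s1
      aln$s_end <- s2
      best <- aln
    }
  }
  best
}

search_translated <- function(reads, database, params, k) {
  db_seqs <- toupper(database$sequence)
  n_db <- sum(nchar(db_seqs))
  idx <- kmer_index(db_seqs, k)
  if (is.null(idx)) stop("no indexable database sequence", call. = FALSE)
  out <- vector("list", nrow(reads))
  for (r in seq_len(nrow(reads))) {
    read_seq <- toupper(reads$sequence[[r]])
    L <- nchar(read_seq)
    if (L < 3L * k) next
    frames <- translate_frames(read_seq)
    m_q <- max(1L, L %/% 3L)
    hit_rows <- list()
    for (fi in seq_len(nrow(frames))) {
      pep <- frames$peptide[[fi]]
      if (!nzchar(pep)) next
      # split at stop codons; search each segment independently
      segs <- stop_segments(pep, k)
      for (sg in seq_len(nrow(segs))) {
        seg <- segs$seq[[sg]]
        starts <- seq_len(nchar(seg) - k + 1L)
        kmers <- substring(seg, starts, starts + k - 1L)
        gid <- match(unique(kmers), names(idx$index))
        rows <- unlist(idx$index[gid[!is.na(gid)]], use.names = FALSE)
        if (length(rows) == 0L) next
        for (si in unique(idx$seq[rows])) {
          aln <- sw_align_cpp(seg, db_seqs[[si]],
                              params$scoring$matrix, params$scoring$alphabet,
                              params$scoring$gap_open,
                              params$scoring$gap_extend)
          if (aln$score <= 0) next
          p1 <- segs$offset[[sg]] + aln$q_start
          p2 <- segs$offset[[sg]] + aln$q_end
          ntc <- frame_to_nt(frames$frame[[fi]], p1, p2, L)
          h <- make_hit(reads$id[[r]], database$id[[si]], aln,
                        aln$s_start, aln$s_end, m = m_q, n = n_db,
                        params = params)
          h$q_start <- ntc[[1L]]
          h$q_end <- ntc[[2L]]
          if (h$evalue <= params$evalue_cutoff) {
            hit_rows[[length(hit_rows) + 1L]] <- h
          }
        }
      }
    }
    if (length(hit_rows)) {
      hh <- do.call(rbind, hit_rows)
      # several frames/segments can hit one subject; keep the best per subject
      hh <- hh[order(hh$evalue, -hh$bit_score, hh$subject_id), , drop = FALSE]
      hh <- hh[!duplicated(hh$subject_id), , drop = FALSE]
      out[[r]] <- hh
    }
  }
  finish_hits(out)
}

stop_segments <- function(pep, k) {
  parts <- strsplit(pep, "*", fixed = TRUE)[[1]]
  if (length(parts) == 0L) parts <- ""
  offs <- cumsum(c(0L, nchar(parts[-length(parts)]) + 1L))
  keep <- nchar(parts) >= k
  data.frame(seq = parts[keep], offset = offs[keep], stringsAsFactors = FALSE)
}

finish_hits <- function(out) {
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  hits$score <- NULL
  rownames(hits) <- NULL
  hits
}

#' Run a homology search (built-in or external)
#'
#' Either runs the built-in [seeded_search()] or ingests a pre-computed
#' 12-column tabular hit file from an external aligner, applying the same
#' E-value cutoff so the downstream contract is identical.
#'
#' @param reads Read data frame.
#' @param database Database data frame (built-in path).
#' @param params A [search_params()].
#' @param external_hits Optional path to an external tabular hit file;
#'   when given, the built-in searcher is not run.
#' @return A hit data frame filtered to `evalue <= evalue_cutoff`.
#' @export
run_search <- function(reads, database = NULL, params = search_params(),
                       external_hits = NULL) {
  stopifnot(inherits(params, "search_params"))
  if (!is.null(external_hits)) {
    hits <- read_hit_table(external_hits)
    hits <- hits[hits$evalue <= params$evalue_cutoff, , drop = FALSE]
    if (nrow(hits) > 0L && nrow(reads) > 0L &&
        !any(hits$query_id %in% reads$id)) {
      warning("external hit table shares no query ids with the read set",
              call. = FALSE)
    }
    # hits naming reads outside the set are unusable downstream
    hits <- hits[hits$query_id %in% reads$id, , drop = FALSE]
    return(order_hits(hits, reads$id))
  }
  if (is.null(database)) stop("either a database or external_hits is required",
                              call. = FALSE)
  seeded_search(reads, database, params)
}
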