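# Pairwise alignment engine: optimal global (Needleman-Wunsch) and local
# (Smith-Waterman) alignment under affine gap penalties, with the identity /
# similarity / coverage metrics used throughout the pipeline, and a
# Karlin-Altschul style e-value surrogate for local searches. This is the
# desk-scale exhaustive search engine behind orthology, TE classification,
# ANIb and the metagenome screen.
#

PROTEIN_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                      "F","P","S","T","W","Y","V","B","Z","X","*")
DNA_ALPHABET <- c("A","C","G","T","N")

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62[PROTEIN_ALPHABET, PROTEIN_ALPHABET]
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})

#' Scoring scheme for pairwise alignment
#'
#' Protein alignments default to BLOSUM62 with affine gap penalties
#' open = 11, extend = 1 (a gap of length k costs 11 + k). Nucleotide
#' alignments default to match +1 / mismatch -2 with open = 5, extend = 2.
#' The Karlin-Altschul parameters attached to each scheme (lambda, K) are
#' the published gapped values for these scoring systems and feed the
#' e-value surrogate of [local_align()]; only the ordering and thresholding
#' behaviour of those e-values is relied upon downstream.
#'
#' @param type "protein" or "nucleotide"
#' @param match,mismatch nucleotide match/mismatch scores (ignored for protein)
#' @param gap_open,gap_extend positive gap penalties; `NULL` picks the
#'   type-specific default
#' @return an object of class `scoring_scheme`
#' @export
scoring_scheme <- function(type = c("protein", "nucleotide"),
                           match = 1L, mismatch = -2L,
                           gap_open = NULL, gap_extend = NULL) {
  type <- match.arg(type)
  if (type == "protein") {
    mat <- .blosum62()
    alphabet <- PROTEIN_ALPHABET
    gap_open <- gap_open %||% 11L
    gap_extend <- gap_extend %||% 1L
    karlin <- c(lambda = 0.267, K = 0.041)
  } else {
    alphabet <- DNA_ALPHABET
    mat <- matrix(as.integer(mismatch), 5, 5,
                  dimnames = list(alphabet, alphabet))
    diag(mat) <- as.integer(match)
    mat["N", ] <- 0L; mat[, "N"] <- 0L
    gap_open <- gap_open %||% 5L
    gap_extend <- gap_extend %||% 2L
    karlin <- c(lambda = 1.28, K = 0.46)
  }
  stopifnot(gap_open > 0, gap_extend > 0, isSymmetric(unname(mat)))
  structure(list(type = type, alphabet = alphabet, matrix = mat,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 karlin = karlin),
            class = "scoring_scheme")
}

# map a sequence string to 0-based codes into the scheme alphabet
encode_seq <- function(x, scheme) {
  ch <- chars(toupper(x))
  idx <- match(ch, scheme$alphabet)
  if (anyNA(idx)) {
    bad <- unique(ch[is.na(idx)])
    stopf("sequence contains letters outside the %s alphabet: %s",
          scheme$type, paste(bad, collapse = ","))
  }
  idx - 1L
}

decode_aln <- function(codes, scheme) {
  out <- character(length(codes))
  gap <- codes < 0
  out[gap] <- "-"
  out[!gap] <- scheme$alphabet[codes[!gap] + 1L]
  cc(out)
}

.check_pair <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1, is.character(b), length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) stopf("sequences must be non-empty")
}

.metrics <- function(sa, sb, scheme, a_len, b_len, a_cons, b_cons) {
  ca <- chars(sa); cb <- chars(sb)
  ncol_aln <- length(ca)
  if (ncol_aln == 0) {
    return(list(identity = 0, similarity = 0,
                qcov = 0, scov = 0))
  }
  ident <- sum(ca == cb & ca != "-")
  nongap <- ca != "-" & cb != "-"
  sim <- 0L
  if (any(nongap)) {
    ia <- match(ca[nongap], scheme$alphabet)
    ib <- match(cb[nongap], scheme$alphabet)
    sim <- sum(scheme$matrix[cbind(ia, ib)] > 0)
  }
  list(identity = ident / ncol_aln,
       similarity = sim / ncol_aln,
       qcov = a_cons / a_len,
       scov = b_cons / b_len)
}

.result <- function(raw, scheme, a, b, local, search_space = NULL) {
  sa <- decode_aln(raw$a_aln, scheme)
  sb <- decode_aln(raw$b_aln, scheme)
  a_cons <- sum(raw$a_aln >= 0)
  b_cons <- sum(raw$b_aln >= 0)
  m <- .metrics(sa, sb, scheme, nchar(a), nchar(b), a_cons, b_cons)
  ev <- NA_real_
  if (local) {
    n <- search_space %||% nchar(b)
    ev <- evalue_surrogate(raw$score, nchar(a), n, scheme)
  }
  structure(list(
    aligned_query = sa, aligned_subject = sb,
    score = raw$score,
    identity_fraction = m$identity,
    similarity_fraction = m$similarity,
    query_coverage = m$qcov,
    subject_coverage = m$scov,
    query_range = c(raw$a_start, raw$a_end),
    subject_range = c(raw$b_start, raw$b_end),
    evalue = ev,
    mode = if (local) "local" else "global"
  ), class = "alignment_result")
}

#' Optimal global alignment (Needleman-Wunsch, affine gaps)
#'
#' Deterministic traceback: on ties the diagonal move is preferred, then the
#' move consuming a query residue, then the move consuming a subject residue.
#'
#' @param a,b sequences (single strings)
#' @param scheme a [scoring_scheme()]; default protein/BLOSUM62
#' @return an `alignment_result` with aligned strings, raw score, identity
#'   and similarity fractions (denominator = all alignment columns including
#'   gap columns) and coverages
#' @export
global_align <- function(a, b, scheme = scoring_scheme("protein")) {
  .check_pair(a, b)
  raw <- cpp_align(encode_seq(a, scheme), encode_seq(b, scheme),
                   scheme$matrix, scheme$gap_open, scheme$gap_extend, FALSE)
  .result(raw, scheme, a, b, local = FALSE)
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' @inheritParams global_align
#' @param search_space effective subject/database length used for the
#'   e-value surrogate (defaults to `nchar(b)`); pass the summed database
#'   length when `b` is one record of a larger search
#' @return an `alignment_result`; `evalue` holds the Karlin-Altschul style
#'   significance surrogate `K*m*n*exp(-lambda*score)`
#' @export
local_align <- function(a, b, scheme = scoring_scheme("protein"),
                        search_space = NULL) {
  .check_pair(a, b)
  raw <- cpp_align(encode_seq(a, scheme), encode_seq(b, scheme),
                   scheme$matrix, scheme$gap_open, scheme$gap_extend, TRUE)
  .result(raw, scheme, a, b, local = TRUE, search_space = search_space)
}

#' Identity fraction of an alignment result
#'
#' Convention used package-wide: identical columns divided by the total
#' number of alignment columns, gap columns included in the denominator.
#'
#' @param result an `alignment_result`
#' @return fraction in `[0, 1]`
#' @export
identity_fraction <- function(result) {
  stopifnot(inherits(result, "alignment_result"))
  result$identity_fraction
}

#' Karlin-Altschul style e-value surrogate
#'
#' @param score raw local alignment score
#' @param m query length
#' @param n subject/database length
#' @param scheme scoring scheme carrying (lambda, K)
#' @return expected chance-hit count surrogate
#' @export
evalue_surrogate <- function(score, m, n, scheme) {
  ka <- scheme$karlin
  unname(ka["K"] * m * n * exp(-ka["lambda"] * score))
}

# score at or above which the surrogate e-value is <= cutoff
score_for_evalue <- function(cutoff, m, n, scheme) {
  ka <- scheme$karlin
  unname((log(ka["K"] * m * n) - log(cutoff)) / ka["lambda"])
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<%s alignment> score=%d identity=%.3f similarity=%.3f qcov=%.2f scov=%.2f\n",
              x$mode, x$score, x$identity_fraction, x$similarity_fraction,
              x$query_coverage, x$subject_coverage))
  cat(" ", x$aligned_query, "\n ", x$aligned_subject, "\n", sep = "")
  invisible(x)
}

#' Translate reads in all six frames
#'
#' @param reads `DNAStringSet` or named character vector of reads
#' @return a `data.table` with columns `read` (index), `frame` (1-3 forward,
#'   4-6 reverse) and `aa` (translated frame, ambiguous codons as X, stops
#'   as `*`)
#' @export
six_frame_translate <- function(reads) {
  if (!is(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  n <- length(reads)
  rc <- Biostrings::reverseComplement(reads)
  out <- vector("list", 6)
  for (f in 1:3) {
    for (strand in 1:2) {
      src <- if (strand == 1) reads else rc
      w <- Biostrings::width(src)
      start <- pmin(f, w + 1L)
      len <- pmax(w - f + 1L, 0L)
      len <- len - (len %% 3L)
      sub <- Biostrings::subseq(src, start = start, width = len)
      aa <- suppressWarnings(Biostrings::translate(sub, if.fuzzy.codon = "X"))
      out[[(strand - 1) * 3 + f]] <- data.table::data.table(
        read = seq_len(n), frame = (strand - 1L) * 3L + f,
        aa = as.character(aa))
    }
  }
  data.table::rbindlist(out)
}

#' Batch Smith-Waterman scores of many queries against one subject
#'
#' Score-only kernel used by the screen and orthology search; same scoring
#' conventions as [local_align()].
#'
#' @param queries character vector of sequences
#' @param subject single subject sequence
#' @param scheme scoring scheme
#' @return integer vector of optimal local scores
#' @export
sw_score_batch <- function(queries, subject, scheme = scoring_scheme("protein")) {
  default_idx <- if (scheme$type == "protein")
    match("X", scheme$alphabet) - 1L else match("N", scheme$alphabet) - 1L
  cpp_sw_scoremax_batch(as.character(queries), subject, scheme$matrix,
                        cc(scheme$alphabet), scheme$gap_open,
                        scheme$gap_extend, default_idx)
}
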