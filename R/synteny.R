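# Anchor-based whole-genome synteny and fragment-based average nucleotide
# identity (ANIb). Anchors are maximal unique exact matches (MUMs): exact
# substrings shared by the two genomes, maximal in length and occurring
# exactly once in each. Matches are enumerated exactly by joining all
# shared k-mers (k = the minimum anchor length) and merging consecutive
# runs along each diagonal; uniqueness is then verified by counting
# occurrences of the full match string in each genome.

#' Find maximal unique match anchors between two sequences
#'
#' Both strands of `b` are searched; reverse-orientation anchors report the
#' position of the matching segment on the forward strand of `b`.
#'
#' @param a,b nucleotide strings (or `annotated_genome`s; replicons are
#'   concatenated with a non-matching spacer and coordinates reported on
#'   the concatenation)
#' @param min_length minimum anchor length (default 20)
#' @return data.frame (start_a, start_b, length, orientation) with 0-based
#'   starts on the forward strands, ordered by `start_a`
#' @export
find_anchors <- function(a, b, min_length = 20L) {
  a <- .as_genome_string(a)
  b <- .as_genome_string(b)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  fwd <- .maximal_matches(a, b, min_length)
  if (nrow(fwd)) fwd$orientation <- "forward"
  rev <- .maximal_matches(a, revcomp(b), min_length)
  if (nrow(rev)) {
    rev$start_b <- nchar(b) - (rev$start_b + rev$length)
    rev$orientation <- "reverse"
  }
  m <- rbind(fwd, rev)
  if (nrow(m) == 0) {
    return(data.frame(start_a = integer(), start_b = integer(),
                      length = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  }
  # uniqueness in both genomes, counting occurrences on both strands (a
  # repeat present in + and - orientation is still a repeat)
  count2 <- function(s, genome) {
    Biostrings::countPattern(s, genome) +
      Biostrings::countPattern(revcomp(s), genome)
  }
  keep <- vapply(seq_len(nrow(m)), function(k) {
    s <- substr(a, m$start_a[k] + 1L, m$start_a[k] + m$length[k])
    count2(s, a) == 1L && count2(s, b) == 1L
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$start_a, m$start_b), , drop = FALSE]
  rownames(m) <- NULL
  m
}

.as_genome_string <- function(x) {
  if (inherits(x, "annotated_genome")) {
    # spacer of N's never matches (k-mers containing N are dropped)
    return(paste(vapply(x$replicons, `[[`, character(1), "sequence"),
                 collapse = cc(rep("N", 50))))
  }
  toupper(x)
}

# k-mer position table of a sequence (0-based), N-containing k-mers dropped
.kmer_table <- function(x, k, col = "ia") {
  n <- nchar(x)
  if (n < k) return(data.table::data.table(kmer = character(), pos = integer()))
  km <- substring(x, 1:(n - k + 1), k:n)
  dt <- data.table::data.table(kmer = km, pos = seq_along(km) - 1L)
  data.table::setnames(dt, "pos", col)
  dt[!grepl("N", kmer, fixed = TRUE)]
}

# all maximal exact matches >= k between a and b (forward), via k-mer join +
# diagonal run merging; exact because every match >= k contains a shared
# k-mer on the same diagonal
.maximal_matches <- function(a, b, k, tab_b = NULL) {
  empty <- data.frame(start_a = integer(), start_b = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(empty)
  dta <- .kmer_table(a, k, "ia")
  dtb <- tab_b %||% .kmer_table(b, k, "ib")
  hits <- merge(dta, dtb, by = "kmer", allow.cartesian = TRUE)
  if (nrow(hits) == 0) return(empty)
  hits[, diag_off := ib - ia]
  data.table::setorder(hits, diag_off, ia)
  hits[, run := cumsum(c(1L, diff(ia) != 1L)), by = diag_off]
  runs <- hits[, .(start_a = min(ia), start_b = min(ib),
                   length = max(ia) - min(ia) + k), by = .(diag_off, run)]
  as.data.frame(runs[, .(start_a, start_b, length)])
}

#' Remove repeat-induced anchors
#'
#' A maximal unique match whose core lies inside a multi-copy repeat (an
#' IS element, say) can still be technically unique because chance
#' flanking-base extensions differ between copy pairs. Such anchors map
#' arbitrary copy pairs onto each other and corrupt block calls. This
#' filter trims `trim` bases from each anchor end and drops the anchor if
#' the remaining core occurs more than once (both strands) in either
#' genome.
#'
#' @param anchors data.frame from [find_anchors()]
#' @param a,b the same genomes (nucleotide strings or `annotated_genome`s)
#' @param trim bases trimmed from each end before the repeat test
#' @return filtered anchor data.frame
#' @export
filter_repeat_anchors <- function(anchors, a, b, trim = 10L) {
  if (nrow(anchors) == 0) return(anchors)
  a <- .as_genome_string(a)
  b <- .as_genome_string(b)
  count2 <- function(s, genome) {
    Biostrings::countPattern(s, genome) +
      Biostrings::countPattern(revcomp(s), genome)
  }
  keep <- vapply(seq_len(nrow(anchors)), function(k) {
    len <- anchors$length[k]
    r <- min(trim, max(0L, (len - 20L) %/% 2L))
    s <- substr(a, anchors$start_a[k] + 1L + r, anchors$start_a[k] + len - r)
    count2(s, a) == 1L && count2(s, b) == 1L
  }, logical(1))
  out <- anchors[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Whole-genome synteny pipeline
#'
#' Anchors, repeat-anchor filtering and chaining in one call.
#'
#' @param a,b genomes (strings or `annotated_genome`s)
#' @param min_length minimum anchor length
#' @param max_gap chaining gap bound
#' @return block data.frame (see [chain_blocks()])
#' @export
synteny_blocks <- function(a, b, min_length = 20L, max_gap = 10000L) {
  anchors <- find_anchors(a, b, min_length)
  anchors <- filter_repeat_anchors(anchors, a, b)
  chain_blocks(anchors, max_gap)
}

#' Chain anchors into synteny blocks
#'
#' Greedy chaining of collinear, orientation-consistent anchors whose
#' inter-anchor gaps (in both genomes) stay within `max_gap`. Every anchor
#' belongs to at most one block. Run [filter_repeat_anchors()] first when
#' the genomes carry multi-copy repeat families.
#'
#' @param anchors data.frame from [find_anchors()]
#' @param max_gap maximum gap between chained anchors (bp, default 10000)
#' @return data.frame of blocks (start_a, end_a, start_b, end_b,
#'   orientation, n_anchors, anchor_bp)
#' @export
chain_blocks <- function(anchors, max_gap = 10000L) {
  empty <- data.frame(start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      orientation = character(), n_anchors = integer(),
                      anchor_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(anchors) == 0) return(empty)
  an <- anchors[order(anchors$start_a, anchors$start_b), , drop = FALSE]
  assigned <- rep(FALSE, nrow(an))
  blocks <- list()
  for (i in seq_len(nrow(an))) {
    if (assigned[i]) next
    chain <- i
    assigned[i] <- TRUE
    last <- i
    for (j in seq_len(nrow(an))) {
      if (assigned[j] || j <= last) next
      same_or <- an$orientation[j] == an$orientation[last]
      gap_a <- an$start_a[j] - (an$start_a[last] + an$length[last])
      collinear <- if (an$orientation[last] == "forward")
        an$start_b[j] >= an$start_b[last] + an$length[last] &&
          an$start_b[j] - (an$start_b[last] + an$length[last]) <= max_gap
      else
        an$start_b[j] + an$length[j] <= an$start_b[last] &&
          an$start_b[last] - (an$start_b[j] + an$length[j]) <= max_gap
      if (same_or && gap_a >= 0 && gap_a <= max_gap && collinear) {
        chain <- c(chain, j)
        assigned[j] <- TRUE
        last <- j
      }
    }
    ch <- an[chain, , drop = FALSE]
    blocks[[length(blocks) + 1]] <- data.frame(
      start_a = min(ch$start_a), end_a = max(ch$start_a + ch$length),
      start_b = min(ch$start_b), end_b = max(ch$start_b + ch$length),
      orientation = ch$orientation[1],
      n_anchors = nrow(ch), anchor_bp = sum(ch$length),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Synteny summary statistics
#'
#' @param blocks data.frame from [chain_blocks()]
#' @param len_a,len_b genome lengths (bp)
#' @return a `synteny_stats` list: n_blocks, inverted fraction, aligned
#'   coverage of each genome (anchored bases / length; a block span can
#'   bridge an unaligned gap, so spans would overcount), mean block
#'   length, plus the dot-plot ready block table
#' @export
synteny_stats <- function(blocks, len_a, len_b) {
  n <- nrow(blocks)
  structure(list(
    n_blocks = n,
    inverted_fraction = if (n) mean(blocks$orientation == "reverse") else 0,
    coverage_a = if (n) sum(blocks$anchor_bp) / len_a else 0,
    coverage_b = if (n) sum(blocks$anchor_bp) / len_b else 0,
    mean_block_length = if (n) mean(blocks$end_a - blocks$start_a) else 0,
    blocks = blocks
  ), class = "synteny_stats")
}

#' @export
print.synteny_stats <- function(x, ...) {
  cat(sprintf("<synteny_stats> %d blocks (%.0f%% inverted), coverage A %.2f / B %.2f, mean block %.0f bp\n",
              x$n_blocks, 100 * x$inverted_fraction, x$coverage_a,
              x$coverage_b, x$mean_block_length))
  invisible(x)
}

#' ANIb configuration
#' @param fragment_length query fragmentation length (default 1020 bp)
#' @param min_identity minimum fragment identity fraction (default 0.30)
#' @param min_alignable minimum alignable fraction of the fragment (0.70)
#' @return an `anib_config`
#' @export
anib_config <- function(fragment_length = 1020L, min_identity = 0.30,
                        min_alignable = 0.70) {
  structure(list(fragment_length = as.integer(fragment_length),
                 min_identity = min_identity, min_alignable = min_alignable),
            class = "anib_config")
}

# best local alignment of one fragment against the reference, localized by
# exact seed matches (the reference window around the densest seed diagonal)
.anib_fragment_identity <- function(frag, targets, config, scheme, seed_k = 15L) {
  best <- NULL
  for (t in targets) {
    m <- .maximal_matches(frag, t$seq, seed_k, tab_b = t$tab)
    target <- t$seq
    if (nrow(m) == 0) next
    # window around the longest seed
    top <- m[which.max(m$length), ]
    centre <- top$start_b + top$length %/% 2 - (top$start_a + top$length %/% 2)
    lo <- max(0L, centre - nchar(frag) %/% 2)
    hi <- min(nchar(target), centre + nchar(frag) + nchar(frag) %/% 2)
    window <- substr(target, lo + 1L, hi)
    al <- local_align(frag, window, scheme)
    if (is.null(best) || al$score > best$score) best <- al
  }
  if (is.null(best)) return(NULL)
  alignable <- best$query_coverage
  if (alignable >= config$min_alignable &&
      best$identity_fraction >= config$min_identity) {
    return(best$identity_fraction)
  }
  NULL
}

# one-directional ANIb: mean identity of accepted query fragments
.anib_oneway <- function(query, ref, config, scheme) {
  n <- nchar(query)
  starts <- seq(1L, n, by = config$fragment_length)
  ref_rc <- revcomp(ref)
  seed_k <- 15L
  targets <- list(list(seq = ref, tab = .kmer_table(ref, seed_k, "ib")),
                  list(seq = ref_rc, tab = .kmer_table(ref_rc, seed_k, "ib")))
  ids <- c()
  n_frag <- 0L
  for (s in starts) {
    frag <- substr(query, s, min(n, s + config$fragment_length - 1L))
    if (nchar(frag) < 100L) next
    n_frag <- n_frag + 1L
    id <- .anib_fragment_identity(frag, targets, config, scheme)
    if (!is.null(id)) ids <- c(ids, id)
  }
  list(mean_identity = if (length(ids)) 100 * mean(ids) else NA_real_,
       accepted = length(ids), fragments = n_frag)
}

#' BLAST-style average nucleotide identity (ANIb)
#'
#' The query genome is cut into consecutive fragments (default 1,020 bp),
#' each is locally aligned to the reference (both strands), and fragments
#' with identity >= 30% over >= 70% of their length contribute their
#' identity. The mean is computed in both directions and averaged.
#'
#' @param genome_a,genome_b nucleotide strings or `annotated_genome`s
#' @param config an [anib_config()]
#' @return an `ani_result`: list with `ani` (percent, NA when not
#'   comparable), per-direction means, accepted-fragment fractions, and
#'   `comparable`
#' @export
anib <- function(genome_a, genome_b, config = anib_config()) {
  a <- .as_genome_string(genome_a)
  b <- .as_genome_string(genome_b)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  scheme <- scoring_scheme("nucleotide")
  ab <- .anib_oneway(a, b, config, scheme)
  ba <- .anib_oneway(b, a, config, scheme)
  comparable <- ab$accepted > 0 && ba$accepted > 0
  structure(list(
    ani = if (comparable) mean(c(ab$mean_identity, ba$mean_identity)) else NA_real_,
    ani_ab = ab$mean_identity, ani_ba = ba$mean_identity,
    accepted_fraction_ab = ab$accepted / max(ab$fragments, 1),
    accepted_fraction_ba = ba$accepted / max(ba$fragments, 1),
    comparable = comparable
  ), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  if (x$comparable) {
    cat(sprintf("<ani_result> ANIb = %.2f%% (A->B %.2f, B->A %.2f; accepted %.0f%%/%.0f%%)\n",
                x$ani, x$ani_ab, x$ani_ba, 100 * x$accepted_fraction_ab,
                100 * x$accepted_fraction_ba))
  } else {
    cat("<ani_result> not comparable (no accepted fragments)\n")
  }
  invisible(x)
}
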