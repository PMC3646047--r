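# Bidirectional best-hit orthology with global-identity filtering,
# pan-genome partitioning, single-copy marker selection for multilocus
# sequence analysis (MLSA), and distance-based neighbor-joining trees.
#
# The ortholog criterion: reciprocal best local-alignment hits at
# significance < 1e-10, then a Needleman-Wunsch global identity filter at
# 30% to remove false hits based on short local alignments of conserved
# domains; pairs at >= 60% identity are marked high-confidence.

#' Orthology configuration
#'
#' @param evalue_cutoff significance cutoff for best hits (default 1e-10;
#'   hits must be strictly below it)
#' @param identity_cutoff minimum global identity for an ortholog (0.30)
#' @param high_identity_cutoff identity at which a pair is flagged
#'   high-confidence (0.60)
#' @return an `orthology_config`
#' @export
orthology_config <- function(evalue_cutoff = 1e-10,
                             identity_cutoff = 0.30,
                             high_identity_cutoff = 0.60) {
  stopifnot(evalue_cutoff > 0,
            identity_cutoff > 0, identity_cutoff <= 1,
            high_identity_cutoff > 0, high_identity_cutoff <= 1)
  structure(list(evalue_cutoff = evalue_cutoff,
                 identity_cutoff = identity_cutoff,
                 high_identity_cutoff = high_identity_cutoff),
            class = "orthology_config")
}

# accept an annotated_genome, an extract_proteome() data.frame, or a named
# character vector; always return a sorted named character vector
.as_proteome <- function(x) {
  if (inherits(x, "annotated_genome")) x <- proteome_seqs(x)
  if (is.data.frame(x)) x <- stats::setNames(x$sequence, x$protein_id)
  stopifnot(is.character(x))
  if (length(x) == 0) return(stats::setNames(character(0), character(0)))
  stopifnot(!is.null(names(x)))
  x[order(names(x))]
}

#' Per-query best hits between two proteomes
#'
#' All-vs-all local alignment; for each query the subject with maximal
#' score whose significance is below the cutoff, ties broken by higher
#' global identity then lexicographic subject id. The e-value search space
#' is the summed subject proteome length (database convention).
#'
#' @param proteome_a,proteome_b proteomes (named character vectors,
#'   [extract_proteome()] frames, or `annotated_genome`s)
#' @param config an [orthology_config()]
#' @return data.frame (query, subject, score, evalue) with one row per
#'   query that has a qualifying hit
#' @export
best_hits <- function(proteome_a, proteome_b, config = orthology_config()) {
  a <- .as_proteome(proteome_a)
  b <- .as_proteome(proteome_b)
  if (length(a) == 0 || length(b) == 0) stopf("empty proteome")
  scheme <- scoring_scheme("protein")
  db_len <- sum(nchar(b))
  scores <- matrix(0L, length(a), length(b),
                   dimnames = list(names(a), names(b)))
  for (j in seq_along(b)) {
    scores[, j] <- sw_score_batch(unname(a), b[[j]], scheme)
  }
  rows <- vector("list", length(a))
  for (i in seq_along(a)) {
    ev <- evalue_surrogate(scores[i, ], nchar(a[[i]]), db_len, scheme)
    ok <- which(ev < config$evalue_cutoff)
    if (length(ok) == 0) next
    top <- ok[scores[i, ok] == max(scores[i, ok])]
    if (length(top) > 1) {
      ids <- vapply(top, function(j)
        global_align(a[[i]], b[[j]], scheme)$identity_fraction, numeric(1))
      top <- top[order(-ids, names(b)[top])]
    }
    j <- top[1]
    rows[[i]] <- data.frame(query = names(a)[i], subject = names(b)[j],
                            score = scores[i, j], evalue = ev[j],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(query = character(), subject = character(),
               score = integer(), evalue = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bidirectional best-hit orthologs with global-identity filter
#'
#' Keeps (a, b) iff a's best hit is b and b's best hit is a, computes the
#' Needleman-Wunsch global identity of each reciprocal pair, drops pairs
#' below the identity cutoff and classifies the rest.
#'
#' @inheritParams best_hits
#' @return data.frame (query, subject, identity, class) sorted by query;
#'   class is "ortholog" or "high_confidence"
#' @export
bbh_orthologs <- function(proteome_a, proteome_b, config = orthology_config()) {
  a <- .as_proteome(proteome_a)
  b <- .as_proteome(proteome_b)
  ab <- best_hits(a, b, config)
  ba <- best_hits(b, a, config)
  back <- stats::setNames(ba$subject, ba$query)
  keep <- !is.na(back[ab$subject]) & back[ab$subject] == ab$query
  pairs <- ab[keep, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(data.frame(query = character(), subject = character(),
                      identity = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  }
  scheme <- scoring_scheme("protein")
  pairs$identity <- vapply(seq_len(nrow(pairs)), function(k)
    global_align(a[[pairs$query[k]]], b[[pairs$subject[k]]],
                 scheme)$identity_fraction, numeric(1))
  pairs <- pairs[pairs$identity >= config$identity_cutoff, , drop = FALSE]
  pairs$class <- ifelse(pairs$identity >= config$high_identity_cutoff,
                        "high_confidence", "ortholog")
  out <- pairs[order(pairs$query), c("query", "subject", "identity", "class")]
  rownames(out) <- NULL
  out
}

# all pairwise ortholog tables for a named list of proteomes
.ortholog_tables <- function(proteomes, config) {
  gids <- names(proteomes)
  tabs <- list()
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (i >= j) next
    tabs[[paste(gids[i], gids[j], sep = "|")]] <-
      bbh_orthologs(proteomes[[i]], proteomes[[j]], config)
  }
  tabs
}

.pair_table <- function(tabs, gi, gj) {
  key <- paste(gi, gj, sep = "|")
  if (!is.null(tabs[[key]])) return(tabs[[key]])
  key <- paste(gj, gi, sep = "|")
  t <- tabs[[key]]
  if (is.null(t)) return(NULL)
  data.frame(query = t$subject, subject = t$query,
             identity = t$identity, class = t$class, stringsAsFactors = FALSE)
}

#' Pan-genome partition over a genome set
#'
#' Each gene is labelled: "shared" if it has an ortholog in at least one
#' other genome, "exclusive" if a designated genome pair is given and the
#' gene's only cross-genome orthologs lie within that pair, and "unique"
#' otherwise. Fractions are reported per genome and pooled over the
#' pan-genome (genes, not gene families, are counted).
#'
#' @param genomes named list (>= 2) of proteomes or `annotated_genome`s
#' @param config an [orthology_config()]
#' @param pair optional character vector of two genome ids forming the
#'   designated pair for the exclusive label
#' @return a `pan_genome_partition`: list with `genes` (per-gene labels),
#'   `counts` and `fractions` per genome, and pooled fractions
#' @export
pan_genome <- function(genomes, config = orthology_config(), pair = NULL) {
  stopifnot(length(genomes) >= 2, !is.null(names(genomes)))
  proteomes <- lapply(genomes, .as_proteome)
  gids <- names(proteomes)
  if (!is.null(pair)) stopifnot(length(pair) == 2, all(pair %in% gids))
  tabs <- .ortholog_tables(proteomes, config)
  gene_rows <- list()
  for (g in gids) {
    partners <- lapply(stats::setNames(nm = setdiff(gids, g)), function(h) {
      t <- .pair_table(tabs, g, h)
      unique(t$query)
    })
    genes <- names(proteomes[[g]])
    in_genome <- vapply(stats::setNames(nm = setdiff(gids, g)),
                        function(h) genes %in% partners[[h]],
                        logical(length(genes)))
    if (is.null(dim(in_genome))) in_genome <- matrix(in_genome, nrow = length(genes))
    n_partner <- rowSums(in_genome)
    label <- ifelse(n_partner >= 1, "shared", "unique")
    if (!is.null(pair) && g %in% pair) {
      other <- setdiff(pair, g)
      outside <- setdiff(gids, pair)
      only_pair <- in_genome[, match(other, setdiff(gids, g)), drop = TRUE] &
        (length(outside) == 0 |
           rowSums(in_genome[, match(outside, setdiff(gids, g)), drop = FALSE]) == 0)
      label[label == "shared" & only_pair] <- "exclusive"
    }
    gene_rows[[g]] <- data.frame(genome_id = g, gene = genes, label = label,
                                 stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  counts <- do.call(rbind, lapply(gids, function(g) {
    x <- genes[genes$genome_id == g, ]
    data.frame(genome_id = g,
               n_genes = nrow(x),
               shared = sum(x$label == "shared"),
               exclusive = sum(x$label == "exclusive"),
               unique = sum(x$label == "unique"),
               stringsAsFactors = FALSE)
  }))
  fractions <- counts
  fractions[c("shared", "exclusive", "unique")] <-
    counts[c("shared", "exclusive", "unique")] / counts$n_genes
  pooled <- colSums(counts[c("shared", "exclusive", "unique")]) / sum(counts$n_genes)
  structure(list(genes = genes, counts = counts, fractions = fractions,
                 pooled_fractions = pooled),
            class = "pan_genome_partition")
}

#' @export
print.pan_genome_partition <- function(x, ...) {
  cat("<pan_genome_partition>\n")
  print(x$counts)
  invisible(x)
}

# does gene have a within-genome paralog? one-directional hit above cutoffs
.has_paralog <- function(gene, proteome, config, scheme, db_len) {
  self <- proteome[[gene]]
  others <- proteome[setdiff(names(proteome), gene)]
  if (length(others) == 0) return(FALSE)
  sc <- sw_score_batch(unname(others), self, scheme)
  ev <- evalue_surrogate(sc, nchar(others), db_len, scheme)
  cand <- which(ev < config$evalue_cutoff)
  for (k in cand) {
    id <- global_align(others[[k]], self, scheme)$identity_fraction
    if (id >= config$identity_cutoff) return(TRUE)
  }
  FALSE
}

#' Single-copy MLSA marker selection
#'
#' A gene of the focal (first) genome is a marker iff it has exactly one
#' ortholog in every other genome (bidirectional best hits give at most
#' one), its partners are mutually orthologous, and no member of the group
#' has a within-genome paralog (another gene of the same genome passing the
#' ortholog e-value and identity cutoffs one-directionally).
#'
#' @param genomes named list of proteomes or `annotated_genome`s (>= 2)
#' @param config an [orthology_config()]
#' @return list of marker groups; each is a named character vector
#'   (genome id -> protein sequence) with attribute `genes` mapping genome
#'   id -> locus. Empty list (with a warning) if no markers are found.
#' @export
single_copy_markers <- function(genomes, config = orthology_config()) {
  stopifnot(length(genomes) >= 2, !is.null(names(genomes)))
  proteomes <- lapply(genomes, .as_proteome)
  gids <- names(proteomes)
  focal <- gids[1]
  tabs <- .ortholog_tables(proteomes, config)
  scheme <- scoring_scheme("protein")
  db_len <- lapply(proteomes, function(p) sum(nchar(p)))
  partner_map <- lapply(stats::setNames(nm = setdiff(gids, focal)), function(h) {
    t <- .pair_table(tabs, focal, h)
    stats::setNames(t$subject, t$query)
  })
  markers <- list()
  for (gene in sort(names(proteomes[[focal]]))) {
    partners <- vapply(partner_map, function(pm) pm[gene] %||% NA_character_,
                       character(1))
    if (anyNA(partners)) next
    group <- c(stats::setNames(gene, focal), partners)
    # partners mutually orthologous
    ok <- TRUE
    non_focal <- setdiff(gids, focal)
    if (length(non_focal) >= 2) {
      for (i in seq_along(non_focal)) for (j in seq_along(non_focal)) {
        if (i >= j) next
        t <- .pair_table(tabs, non_focal[i], non_focal[j])
        hit <- t$subject[t$query == group[[non_focal[i]]]]
        if (length(hit) != 1 || hit != group[[non_focal[j]]]) ok <- FALSE
      }
    }
    if (!ok) next
    # no paralogs anywhere in the group
    for (g in gids) {
      if (.has_paralog(group[[g]], proteomes[[g]], config, scheme, db_len[[g]])) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    seqs <- vapply(gids, function(g) proteomes[[g]][[group[[g]]]], character(1))
    m <- stats::setNames(seqs, gids)
    attr(m, "genes") <- group
    markers[[gene]] <- m
  }
  if (length(markers) == 0) warnf("no single-copy markers found")
  markers
}

# ---- center-star multiple alignment ------------------------------------

# align each sequence to the center with NW and merge into one MSA;
# deterministic: center = longest sequence (ties by name order)
center_star_align <- function(seqs, scheme = scoring_scheme("protein")) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (length(seqs) == 1) return(stats::setNames(seqs, names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  center <- names(seqs)[ord[1]]
  others <- setdiff(names(seqs), center)
  alns <- lapply(stats::setNames(nm = others), function(nm)
    global_align(seqs[[center]], seqs[[nm]], scheme))
  # insertion length after each center position (0 = before first residue)
  clen <- nchar(seqs[[center]])
  ins <- integer(clen + 1)
  gap_runs <- function(ca) {
    # per center position: number of alignment columns where center is gapped
    pos <- 0L
    runs <- integer(clen + 1)
    for (ch in ca) {
      if (ch == "-") runs[pos + 1L] <- runs[pos + 1L] + 1L else pos <- pos + 1L
    }
    runs
  }
  runs_list <- lapply(alns, function(al) gap_runs(chars(al$aligned_query)))
  for (r in runs_list) ins <- pmax(ins, r)
  ncol_out <- clen + sum(ins)
  # expanded center row
  expand_row <- function(ca, cb, runs) {
    # walk columns; pad each inter-residue slot to ins[slot]
    out <- character(ncol_out)
    oi <- 0L
    pos <- 0L
    slot_used <- 0L
    flush_slot <- function(oi, used, slot) {
      extra <- ins[slot + 1L] - used
      if (extra > 0) {
        out[(oi + 1L):(oi + extra)] <<- "-"
        oi <- oi + extra
      }
      oi
    }
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        out[oi + 1L] <- cb[k]
        oi <- oi + 1L
        slot_used <- slot_used + 1L
      } else {
        oi <- flush_slot(oi, slot_used, pos)
        slot_used <- 0L
        out[oi + 1L] <- cb[k]
        oi <- oi + 1L
        pos <- pos + 1L
      }
    }
    oi <- flush_slot(oi, slot_used, pos)
    cc(out)
  }
  res <- stats::setNames(vector("character", length(seqs)), names(seqs))
  # center row: its own residues with full insertion padding
  ca_center <- chars(seqs[[center]])
  res[[center]] <- expand_row(ca_center, ca_center, integer(clen + 1))
  for (nm in others) {
    al <- alns[[nm]]
    res[[nm]] <- expand_row(chars(al$aligned_query), chars(al$aligned_subject),
                            NULL)
  }
  res[order(names(res))]
}

#' Concatenate aligned single-copy markers for MLSA
#'
#' Each marker group is multiple-aligned by deterministic center-star
#' progressive alignment (pairwise global alignments to the longest
#' member), the per-marker alignments are concatenated in sorted marker
#' order, and every column containing at least one gap is removed.
#'
#' @param markers marker list from [single_copy_markers()]
#' @param scheme protein scoring scheme
#' @return an `mlsa_alignment`: list with `alignment` (named character
#'   vector of equal-length gap-free rows), `n_markers`, `marker_lengths`
#'   (gap-free columns contributed per marker) and `removed_columns`
#' @export
mlsa_concat <- function(markers, scheme = scoring_scheme("protein")) {
  stopifnot(length(markers) >= 1)
  markers <- markers[order(names(markers))]
  taxa <- sort(names(markers[[1]]))
  per_marker <- lapply(markers, function(m) center_star_align(m, scheme))
  kept_lengths <- integer(length(markers))
  removed <- 0L
  pieces <- lapply(seq_along(per_marker), function(k) {
    msa <- per_marker[[k]][taxa]
    mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
    gap_cols <- apply(mat == "-", 2, any)
    kept_lengths[k] <<- sum(!gap_cols)
    removed <<- removed + sum(gap_cols)
    mat[, !gap_cols, drop = FALSE]
  })
  full <- do.call(cbind, pieces)
  if (ncol(full) == 0) stopf("no columns left after gap filtering")
  structure(list(
    alignment = stats::setNames(apply(full, 1, cc), taxa),
    n_markers = length(markers),
    marker_lengths = stats::setNames(kept_lengths, names(markers)),
    removed_columns = removed
  ), class = "mlsa_alignment")
}

#' P-distance matrix from a gap-free alignment
#'
#' @param alignment named character vector of equal-length rows (e.g.
#'   `mlsa_concat(...)$alignment`)
#' @return symmetric matrix of 1 - identity
#' @export
p_distance <- function(alignment) {
  if (inherits(alignment, "mlsa_alignment")) alignment <- alignment$alignment
  n <- length(alignment)
  stopifnot(n >= 2, length(unique(nchar(alignment))) == 1)
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- mean(mat[i, ] != mat[j, ])
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration (via ape) with deterministic
#' input ordering: taxa are sorted by label before clustering so that tied
#' joins resolve identically across runs.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal
#' @param labels optional label vector overriding `rownames(d)`
#' @return an `ape::phylo` tree
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  stopifnot(nrow(d) == ncol(d), !is.null(rownames(d)))
  if (nrow(d) < 3) stopf("neighbor-joining needs at least 3 taxa")
  if (any(d < 0) || any(abs(diag(d)) > 1e-12) || any(abs(d - t(d)) > 1e-8))
    stopf("distance matrix must be symmetric, non-negative, zero-diagonal")
  ord <- order(rownames(d))
  ape::nj(stats::as.dist(d[ord, ord]))
}

#' Write a tree in Newick format
#' @param tree `phylo` object
#' @param path output file
#' @return invisibly, `path`
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
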