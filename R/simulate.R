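# Seeded synthetic-data generators. Every generator is deterministic for a
# fixed seed and emits a truth table that is re-verifiable from the emitted
# sequences alone. Genome pairs emulate the mechanisms of highly plastic
# genomes: planted 1:1 orthologs at controlled protein identity, insertion
# sequence (IS) families in multiple copies, GC-shifted islands of foreign
# genes, and TE-anchored inversions. Metagenomes emulate pyrosequencing-like
# (short, right-skewed, mean < 150 bp) and Sanger-like (700-1000 bp) read
# regimes with planted rhodopsin-gene fragments over an i.i.d. background.

# run code under a local RNG state
.local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
          "F","P","S","T","W","Y","V")

#' Random DNA string
#' @param n length
#' @param gc GC fraction
#' @return nucleotide string
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  cc(sample(c("A", "T", "G", "C"), n, replace = TRUE,
            prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)))
}

#' Random protein sequence (starts with M)
#' @param n length in aa
#' @return protein string
#' @keywords internal
random_protein <- function(n) {
  cc(c("M", sample(AA20, n - 1, replace = TRUE)))
}

# synonymous codon sets per amino acid, bacterial code
.codon_sets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), gc)
    }
    cache
  }
})

#' Back-translate a protein with weighted synonymous codon choice
#'
#' @param aa protein string (no stops)
#' @param gc_weight synonymous codon weight multiplier per G/C base:
#'   1 = uniform, < 1 biases toward AT-rich codons, > 1 toward GC-rich
#' @return in-frame nucleotide string (no stop codon appended)
#' @export
back_translate <- function(aa, gc_weight = 1) {
  sets <- .codon_sets()
  cods <- vapply(chars(aa), function(a) {
    syn <- sets[[a]]
    if (is.null(syn)) stopf("cannot back-translate residue '%s'", a)
    gcn <- vapply(strsplit(syn, ""), function(x) sum(x %in% c("G", "C")), numeric(1))
    w <- gc_weight^gcn
    sample(syn, 1, prob = w / sum(w))
  }, character(1))
  cc(cods)
}

#' Mutate a protein to a target global identity
#'
#' Substitution-only by default: the exact number of positions needed to
#' land on the target is replaced with different residues, so the realized
#' Needleman-Wunsch identity (full-column convention) equals the target to
#' within half a residue. With `indel_rate > 0` up to that fraction of
#' positions is additionally inserted/deleted and the result is re-measured
#' and re-tried (bounded) until the realized identity is within
#' `tolerance` of the target.
#'
#' @param sequence protein string
#' @param target target identity in (0, 1]
#' @param seed optional seed (local RNG scope)
#' @param indel_rate at most this fraction of positions as indels (<= 0.05)
#' @param tolerance acceptance half-width on realized identity (0.02)
#' @return mutated sequence with attribute `realized_identity`
#' @export
mutate_to_identity <- function(sequence, target, seed = NULL,
                               indel_rate = 0, tolerance = 0.02) {
  stopifnot(target > 0, target <= 1, indel_rate <= 0.05)
  run <- function() {
    L <- nchar(sequence)
    if (target == 1 && indel_rate == 0) {
      out <- sequence
      attr(out, "realized_identity") <- 1
      return(out)
    }
    scheme <- scoring_scheme("protein")
    for (attempt in 1:25) {
      ca <- chars(sequence)
      k <- round((1 - target) * L)
      if (k > 0) {
        pos <- sample(L, k)
        ca[pos] <- vapply(ca[pos], function(x) sample(setdiff(AA20, x), 1),
                          character(1))
      }
      if (indel_rate > 0) {
        ni <- sample(0:max(0, floor(indel_rate * L)), 1)
        if (ni > 0) {
          for (z in seq_len(ni)) {
            if (stats::runif(1) < 0.5 && length(ca) > 10) {
              ca <- ca[-sample(length(ca), 1)]
            } else {
              at <- sample(length(ca), 1)
              ca <- append(ca, sample(AA20, 1), after = at)
            }
          }
        }
      }
      out <- cc(ca)
      realized <- if (indel_rate > 0 || k > 0)
        global_align(sequence, out, scheme)$identity_fraction else 1
      if (abs(realized - target) <= tolerance) {
        attr(out, "realized_identity") <- realized
        return(out)
      }
    }
    stopf("could not reach target identity %.2f within 25 attempts", target)
  }
  if (is.null(seed)) run() else .local_seed(seed, run())
}

#' Synthetic TE reference library
#'
#' One transposase-like random protein per IS family plus a slightly
#' diverged second record, labelled with canonical IS family names.
#'
#' @param n_families number of families (<= 8)
#' @param length_aa transposase length
#' @param seed RNG seed
#' @return a [te_library()]
#' @export
simulate_te_library <- function(n_families = 3, length_aa = 280, seed = 1) {
  fams <- c("IS3", "IS5", "IS110", "IS30", "IS66", "IS21", "IS256", "IS481")
  stopifnot(n_families <= length(fams))
  .local_seed(seed, {
    fams <- fams[seq_len(n_families)]
    seqs <- c()
    family <- c()
    for (f in fams) {
      arch <- random_protein(length_aa)
      var <- mutate_to_identity(arch, 0.85)
      s <- stats::setNames(c(arch, as.character(var)),
                           paste0(f, c("_ref1", "_ref2")))
      seqs <- c(seqs, s)
      family <- c(family, f, f)
    }
    te_library(seqs, family)
  })
}

#' Parameters for a synthetic genome pair
#'
#' Defaults describe a small but realistic study condition: a few hundred
#' kb of gene-dense chromosome, orthologs planted at the identity levels
#' that exercise the 30%/60% classification bands, a multi-copy IS
#' complement, GC-shifted foreign-gene islands and TE-anchored inversions.
#'
#' @param n_genes core (orthologous) gene count
#' @param gene_length_range CDS length range in codons
#' @param identity_levels,identity_props planted ortholog protein identity
#'   levels and their mixing proportions (must sum to 1)
#' @param n_te_families,te_copies IS families and copies per family per
#'   genome
#' @param te_copy_identity protein identity of planted copies to the family
#'   archetype (1 = identical copies, the recent-expansion regime)
#' @param n_islands islands planted on genome A
#' @param island_n_genes foreign genes per island
#' @param island_gc_weight synonymous-codon GC weight inside islands (< 1
#'   shifts island GC down)
#' @param n_inversions inverted segments planted in genome B
#' @param te_anchored_inversions flank inverted segments with IS copies
#' @param pseudogene_frac fraction of core genes disrupted to pseudogenes
#'   (per genome, disjoint sets)
#' @param intergenic_range intergenic spacer length range (bp)
#' @param host_gc intergenic GC fraction of the host backbone
#' @param n_rrna,n_trna RNA genes annotated per genome
#' @param seed RNG seed
#' @return a `genome_pair_params`
#' @export
genome_pair_params <- function(n_genes = 60,
                               gene_length_range = c(120, 360),
                               identity_levels = c(0.45, 0.75),
                               identity_props = c(0.5, 0.5),
                               n_te_families = 2,
                               te_copies = 3,
                               te_copy_identity = 1.0,
                               n_islands = 0,
                               island_n_genes = 8,
                               island_gc_weight = 0.35,
                               n_inversions = 0,
                               te_anchored_inversions = TRUE,
                               pseudogene_frac = 0,
                               intergenic_range = c(60, 180),
                               host_gc = 0.55,
                               n_rrna = 2,
                               n_trna = 4,
                               seed = 1) {
  stopifnot(abs(sum(identity_props) - 1) < 1e-8,
            length(identity_levels) == length(identity_props),
            all(identity_levels > 0), all(identity_levels <= 1))
  structure(as.list(environment()), class = "genome_pair_params")
}

# build one replicon sequence + features from a gene plan
.assemble_replicon <- function(plan, name, role = "chromosome") {
  seqs <- character(0)
  feats <- list()
  pos <- 0L
  for (k in seq_len(nrow(plan))) {
    row <- plan[k, ]
    nt <- row$nt[[1]]
    if (row$kind == "spacer") {
      seqs <- c(seqs, nt)
      pos <- pos + nchar(nt)
      next
    }
    placed <- if (row$strand == "-") revcomp(nt) else nt
    seqs <- c(seqs, placed)
    f <- feature(row$kind, pos, pos + nchar(nt), row$strand, row$locus_tag,
                 product = row$product,
                 te_family = row$te_family)
    feats <- c(feats, list(f))
    pos <- pos + nchar(nt)
  }
  replicon(name, cc(seqs), topology = "circular", role = role, features = feats)
}

.plan_row <- function(kind, nt, locus_tag = NA_character_, strand = "+",
                      product = "", te_family = NA_character_,
                      class = kind) {
  data.frame(kind = kind, nt = I(list(nt)), locus_tag = locus_tag,
             strand = strand, product = product, te_family = te_family,
             class = class, stringsAsFactors = FALSE)
}

#' Simulate an annotated genome pair with truth table
#'
#' Genome A is assembled from random core genes, IS-family copies and
#' optional GC-shifted islands of foreign genes; genome B carries the same
#' core genes diverged to the planted protein identity levels (codon-level
#' edits, so nucleotide context is preserved at identity 1), the same IS
#' complement, no islands, and optionally inverted segments (TE-anchored).
#'
#' @param params a [genome_pair_params()]
#' @param te_lib optional [te_library()]; default simulated from the same
#'   seed
#' @return list(genome_a, genome_b, te_library, truth) where truth has
#'   `orthologs` (locus_a, locus_b, target_identity, realized_identity),
#'   `te` (genome_id, locus_tag, family, is_pseudo), `islands`
#'   (genome_id, start, end), `inversions` (start_b, end_b, te_anchored),
#'   `pseudogenes` (genome_id, locus_tag)
#' @export
simulate_genome_pair <- function(params = genome_pair_params(), te_lib = NULL) {
  stopifnot(inherits(params, "genome_pair_params"))
  .local_seed(params$seed + 1000L, {
    p <- params
    if (is.null(te_lib)) te_lib <- simulate_te_library(
      n_families = p$n_te_families, seed = p$seed + 77L)
    fams <- unique(te_lib$family)[seq_len(p$n_te_families)]
    if (p$n_islands > 0 && p$island_n_genes * p$n_islands > 0 &&
        p$n_islands * (p$island_n_genes * 1200) > 5e6) {
      stopf("islands exceed a sensible genome size")
    }

    spacer <- function(gc = p$host_gc)
      random_dna(sample(seq(p$intergenic_range[1], p$intergenic_range[2]), 1), gc)

    # core genes
    lens <- sample(seq(p$gene_length_range[1], p$gene_length_range[2]), p$n_genes,
                   replace = TRUE)
    core_aa <- lapply(lens, random_protein)
    core_nt_a <- vapply(core_aa, function(a) paste0(back_translate(a), "TAA"),
                        character(1))
    levels_idx <- sample(seq_along(p$identity_levels), p$n_genes, replace = TRUE,
                         prob = p$identity_props)
    strands <- sample(c("+", "-"), p$n_genes, replace = TRUE)

    # diverge B genes by codon-level substitution edits of the A genes
    core_nt_b <- character(p$n_genes)
    realized <- numeric(p$n_genes)
    scheme <- scoring_scheme("protein")
    sets <- .codon_sets()
    for (g in seq_len(p$n_genes)) {
      tgt <- p$identity_levels[levels_idx[g]]
      aa <- chars(core_aa[[g]])
      L <- length(aa)
      k <- round((1 - tgt) * L)
      nt <- core_nt_a[g]
      if (k > 0) {
        pos <- sample(2:L, min(k, L - 1)) # keep start codon
        for (q in pos) {
          newaa <- sample(setdiff(AA20, aa[q]), 1)
          cod <- sample(sets[[newaa]], 1)
          substr(nt, (q - 1) * 3 + 1, q * 3) <- cod
          aa[q] <- newaa
        }
      }
      core_nt_b[g] <- nt
      realized[g] <- if (k > 0)
        global_align(core_aa[[g]], cc(aa), scheme)$identity_fraction else 1
    }

    # TE copies: same family archetypes in both genomes, light divergence
    te_arch <- stats::setNames(
      vapply(fams, function(f) te_lib$seqs[[which(te_lib$family == f)[1]]],
             character(1)), fams)
    # one nucleotide archetype per family: copies at identity 1 are exact
    # nucleotide repeats (so no k-mer of a TE is unique in either genome)
    te_nt_arch <- stats::setNames(
      vapply(fams, function(f) paste0(back_translate(te_arch[[f]]), "TAA"),
             character(1)), fams)
    make_te_copy <- function(fam) {
      if (p$te_copy_identity >= 1) return(te_nt_arch[[fam]])
      aa <- as.character(mutate_to_identity(te_arch[[fam]], p$te_copy_identity))
      paste0(back_translate(aa), "TAA")
    }

    # pseudogene selection (disjoint between genomes)
    n_ps <- round(p$pseudogene_frac * p$n_genes)
    ps_a <- if (n_ps > 0) sample(p$n_genes, n_ps) else integer(0)
    ps_b <- if (n_ps > 0) sample(setdiff(seq_len(p$n_genes), ps_a), n_ps) else integer(0)
    disrupt <- function(nt) { # premature stop mid-gene
      ncod <- nchar(nt) %/% 3
      at <- max(2, ncod %/% 2)
      substr(nt, (at - 1) * 3 + 1, at * 3) <- "TAA"
      nt
    }

    # ---- genome A plan ----
    plan_a <- list()
    truth_te <- list()
    add <- function(lst, row) c(lst, list(row))
    for (g in seq_len(p$n_genes)) {
      plan_a <- add(plan_a, .plan_row("spacer", spacer()))
      kind <- if (g %in% ps_a) "pseudogene" else "CDS"
      nt <- if (g %in% ps_a) disrupt(core_nt_a[g]) else core_nt_a[g]
      plan_a <- add(plan_a, .plan_row(kind, nt, sprintf("GA_%04d", g),
                                      strands[g], "hypothetical protein",
                                      class = "core"))
    }
    # TE copies interleaved at random core positions (after genes)
    te_rows_a <- list()
    te_id <- 0L
    for (f in fams) for (cp in seq_len(p$te_copies)) {
      te_id <- te_id + 1L
      tag <- sprintf("GA_TE%03d", te_id)
      te_rows_a <- add(te_rows_a, .plan_row("CDS", make_te_copy(f), tag,
                                            sample(c("+", "-"), 1),
                                            "transposase", te_family = f,
                                            class = "te"))
    }
    # splice TE rows into the plan at random points (not at the ends)
    if (length(te_rows_a)) {
      at <- sort(sample(length(plan_a), length(te_rows_a), replace = TRUE))
      merged <- list()
      ti <- 1L
      for (k in seq_along(plan_a)) {
        merged <- add(merged, plan_a[[k]])
        while (ti <= length(at) && at[ti] == k) {
          merged <- add(merged, .plan_row("spacer", spacer()))
          merged <- add(merged, te_rows_a[[ti]])
          ti <- ti + 1L
        }
      }
      plan_a <- merged
    }
    # islands appended as contiguous blocks with AT-shifted composition
    island_truth <- list()
    island_plans <- list()
    for (isl in seq_len(p$n_islands)) {
      ip <- list()
      ip <- add(ip, .plan_row("spacer", spacer()))
      for (g in seq_len(p$island_n_genes)) {
        aa <- random_protein(sample(seq(p$gene_length_range[1],
                                        p$gene_length_range[2]), 1))
        nt <- paste0(back_translate(aa, gc_weight = p$island_gc_weight), "TAA")
        ip <- add(ip, .plan_row("CDS", nt,
                                sprintf("GA_ISL%d_%03d", isl, g),
                                sample(c("+", "-"), 1),
                                "island protein", class = "island"))
        ip <- add(ip, .plan_row("spacer", random_dna(
          sample(seq(p$intergenic_range[1], p$intergenic_range[2]), 1),
          gc = 0.30)))
        if (g %% 2 == 0) { # TE-rich island interior: tandem IS pair
          for (tcopy in 1:2) {
            te_id <- te_id + 1L
            ip <- add(ip, .plan_row("CDS", make_te_copy(fams[1]),
                                    sprintf("GA_TE%03d", te_id),
                                    sample(c("+", "-"), 1), "transposase",
                                    te_family = fams[1], class = "te"))
            ip <- add(ip, .plan_row("spacer", random_dna(80, gc = 0.30)))
          }
        }
      }
      island_plans[[isl]] <- ip
    }
    # interleave islands into the backbone at separated positions
    if (p$n_islands > 0) {
      # evenly spaced insertion points so islands stay separated by host
      # backbone (merging two adjacent islands is a different condition)
      cutpoints <- round(seq_len(p$n_islands) * length(plan_a) / (p$n_islands + 1))
      cutpoints <- pmin(pmax(cutpoints, 3L), length(plan_a) - 2L)
      merged <- list()
      done <- 0L
      for (k in seq_along(plan_a)) {
        merged <- add(merged, plan_a[[k]])
        hitk <- which(cutpoints == k)
        for (h in hitk) for (row in island_plans[[h]]) merged <- add(merged, row)
      }
      plan_a <- merged
    }
    rna_rows <- function(prefix) {
      out <- list()
      for (z in seq_len(p$n_rrna)) {
        out <- add(out, .plan_row("spacer", spacer()))
        out <- add(out, .plan_row("rRNA", random_dna(1500, p$host_gc),
                                  sprintf("%s_rRNA%02d", prefix, z),
                                  sample(c("+", "-"), 1), "ribosomal RNA",
                                  class = "rna"))
      }
      for (z in seq_len(p$n_trna)) {
        out <- add(out, .plan_row("spacer", spacer()))
        out <- add(out, .plan_row("tRNA", random_dna(76, p$host_gc),
                                  sprintf("%s_tRNA%02d", prefix, z),
                                  sample(c("+", "-"), 1), "transfer RNA",
                                  class = "rna"))
      }
      out
    }
    plan_a <- c(plan_a, rna_rows("GA"))
    plan_a <- do.call(rbind, plan_a)
    rep_a <- .assemble_replicon(plan_a, "chrA")
    # island truth from realized coordinates
    fta <- feature_table(annotated_genome("A", "o", list(rep_a)))
    for (isl in seq_len(p$n_islands)) {
      tags <- fta$locus_tag[grepl(sprintf("^GA_ISL%d_", isl), fta$locus_tag)]
      sub <- fta[fta$locus_tag %in% tags, ]
      island_truth <- add(island_truth,
                          data.frame(genome_id = "A", island = isl,
                                     start = min(sub$start), end = max(sub$end),
                                     stringsAsFactors = FALSE))
    }

    # ---- genome B plan: core genes (diverged), TEs, no islands ----
    plan_b <- list()
    for (g in seq_len(p$n_genes)) {
      plan_b <- add(plan_b, .plan_row("spacer", spacer()))
      kind <- if (g %in% ps_b) "pseudogene" else "CDS"
      nt <- if (g %in% ps_b) disrupt(core_nt_b[g]) else core_nt_b[g]
      plan_b <- add(plan_b, .plan_row(kind, nt, sprintf("GB_%04d", g),
                                      strands[g], "hypothetical protein",
                                      class = "core"))
    }
    te_rows_b <- list()
    for (f in fams) for (cp in seq_len(p$te_copies)) {
      te_id <- te_id + 1L
      te_rows_b <- add(te_rows_b, .plan_row("CDS", make_te_copy(f),
                                            sprintf("GB_TE%03d", te_id),
                                            sample(c("+", "-"), 1),
                                            "transposase", te_family = f,
                                            class = "te"))
    }
    if (length(te_rows_b)) {
      at <- sort(sample(length(plan_b), length(te_rows_b), replace = TRUE))
      merged <- list()
      ti <- 1L
      for (k in seq_along(plan_b)) {
        merged <- add(merged, plan_b[[k]])
        while (ti <= length(at) && at[ti] == k) {
          merged <- add(merged, .plan_row("spacer", spacer()))
          merged <- add(merged, te_rows_b[[ti]])
          ti <- ti + 1L
        }
      }
      plan_b <- merged
    }
    plan_b <- c(plan_b, rna_rows("GB"))
    plan_b <- do.call(rbind, plan_b)
    rep_b <- .assemble_replicon(plan_b, "chrB")

    # ---- inversions in B: reverse-complement disjoint internal segments ----
    inv_truth <- list()
    if (p$n_inversions > 0) {
      seq_b <- rep_b$sequence
      len_b <- nchar(seq_b)
      ftb <- feature_table(annotated_genome("B", "o", list(rep_b)))
      ftb <- ftb[order(ftb$start), ]
      nfeat <- nrow(ftb)
      segs <- list()
      if (p$te_anchored_inversions) {
        # segments between consecutive TE copies that bracket >= 1 core gene
        te_idx <- which(!is.na(ftb$te_family))
        used_up_to <- 0L
        for (z in seq_len(max(0, length(te_idx) - 1))) {
          if (length(segs) >= p$n_inversions) break
          i1 <- te_idx[z]; i2 <- te_idx[z + 1]
          if (i1 <= used_up_to) next
          idx_between <- (i1 + 1):(i2 - 1)
          has_gene <- i2 - i1 >= 2 &&
            any(ftb$kind[idx_between] %in% c("CDS", "pseudogene") &
                  is.na(ftb$te_family[idx_between]))
          if (has_gene) {
            segs[[length(segs) + 1]] <- c(ftb$end[i1], ftb$start[i2])
            used_up_to <- i2
          }
        }
      }
      if (length(segs) < p$n_inversions) {
        # fallback: evenly spaced runs of consecutive features
        need <- p$n_inversions - length(segs)
        taken <- if (length(segs))
          do.call(rbind, segs) else matrix(numeric(0), ncol = 2)
        run_len <- max(2L, nfeat %/% (3L * p$n_inversions))
        starts_idx <- unique(round(seq(2, nfeat - run_len - 1,
                                       length.out = p$n_inversions * 2)))
        for (s0 in starts_idx) {
          if (need == 0) break
          idx_run <- s0:min(nfeat, s0 + run_len - 1)
          s <- ftb$start[s0]; e <- ftb$end[max(idx_run)]
          overlaps <- nrow(taken) > 0 && any(s < taken[, 2] & e > taken[, 1])
          has_gene <- any(ftb$kind[idx_run] %in% c("CDS", "pseudogene") &
                            is.na(ftb$te_family[idx_run]))
          if (!overlaps && has_gene) {
            segs[[length(segs) + 1]] <- c(s, e)
            taken <- rbind(taken, c(s, e))
            need <- need - 1L
          }
        }
      }
      if (length(segs) < p$n_inversions)
        stopf("genome too small for %d inversions", p$n_inversions)
      segs <- segs[seq_len(p$n_inversions)]
      segs <- segs[order(vapply(segs, `[`, numeric(1), 1))]
      features_keep <- list()
      new_seq <- seq_b
      for (sg in segs) {
        s <- sg[1]; e <- sg[2]
        piece <- substr(new_seq, s + 1, e)
        substr(new_seq, s + 1, e) <- revcomp(piece)
        inv_truth <- add(inv_truth, data.frame(
          start_b = s, end_b = e, te_anchored = p$te_anchored_inversions,
          stringsAsFactors = FALSE))
      }
      # remap features: those inside a segment are mirrored and re-stranded
      feats <- rep_b$features
      feats2 <- list()
      for (f in feats) {
        inside <- FALSE
        for (sg in segs) {
          if (f$start >= sg[1] && f$end <= sg[2]) {
            ns <- sg[1] + (sg[2] - f$end)
            ne <- sg[1] + (sg[2] - f$start)
            f$start <- as.integer(ns); f$end <- as.integer(ne)
            f$strand <- if (f$strand == "+") "-" else "+"
            inside <- TRUE
            break
          }
        }
        # features straddling a boundary cannot occur (segments align to
        # feature bounds); spacer DNA between them is inverted silently
        feats2 <- c(feats2, list(f))
      }
      rep_b <- replicon("chrB", new_seq, "circular", "chromosome", feats2)
    }

    genome_a <- annotated_genome("A", "Synthetica borealis", list(rep_a))
    genome_b <- annotated_genome("B", "Synthetica australis", list(rep_b))

    ortho <- data.frame(
      locus_a = sprintf("GA_%04d", seq_len(p$n_genes)),
      locus_b = sprintf("GB_%04d", seq_len(p$n_genes)),
      target_identity = p$identity_levels[levels_idx],
      realized_identity = realized, stringsAsFactors = FALSE)
    ortho$both_coding <- !(seq_len(p$n_genes) %in% c(ps_a, ps_b))
    tea <- plan_a$class == "te"
    teb <- plan_b$class == "te"
    te_truth <- data.frame(
      genome_id = c(rep("A", sum(tea)), rep("B", sum(teb))),
      locus_tag = c(plan_a$locus_tag[tea], plan_b$locus_tag[teb]),
      family = c(plan_a$te_family[tea], plan_b$te_family[teb]),
      stringsAsFactors = FALSE)
    truth <- list(
      orthologs = ortho,
      te = te_truth,
      islands = do.call(rbind, island_truth) %||%
        data.frame(genome_id = character(), island = integer(),
                   start = integer(), end = integer(), stringsAsFactors = FALSE),
      inversions = do.call(rbind, inv_truth) %||%
        data.frame(start_b = integer(), end_b = integer(),
                   te_anchored = logical(), stringsAsFactors = FALSE),
      pseudogenes = data.frame(
        genome_id = c(rep("A", length(ps_a)), rep("B", length(ps_b))),
        locus_tag = c(sprintf("GA_%04d", ps_a), sprintf("GB_%04d", ps_b)),
        stringsAsFactors = FALSE))
    list(genome_a = genome_a, genome_b = genome_b, te_library = te_lib,
         truth = truth)
  })
}

# ---- rhodopsin reference + metagenome generators ------------------------

# canonical subgroup-I residues at the profiled binding positions
.XR_I_RESIDUES <- c("156" = "G", "160" = "T", "194" = "L", "197" = "L",
                    "198" = "A", "201" = "G", "205" = "I")
.XR_II_RESIDUES <- c("156" = "W", "160" = "S", "194" = "F", "197" = "V",
                     "198" = "T", "201" = "L", "205" = "V")

.set_positions <- function(aa, residues) {
  ca <- chars(aa)
  for (p in names(residues)) ca[as.integer(p)] <- residues[[p]]
  cc(ca)
}

#' Synthetic labelled rhodopsin reference set
#'
#' Six main groups with two members each; xanthorhodopsins split into
#' subgroup I (small Gly at the 156-equivalent, intact helix-F binding
#' slot) and subgroup II (bulky Trp at 156, degenerate slot). The first
#' subgroup-I record is the numbering reference for
#' [binding_site_profile()].
#'
#' @param length_aa opsin length (default 240)
#' @param seed RNG seed
#' @return a [rhodopsin_refs()]
#' @export
simulate_rhodopsin_refs <- function(length_aa = 240, seed = 1) {
  stopifnot(length_aa >= 210)
  .local_seed(seed + 500L, {
    seqs <- c(); grp <- c(); sg <- c()
    push <- function(id, s, g, s2 = NA_character_) {
      seqs[[id]] <<- s; grp <<- c(grp, g); sg <<- c(sg, s2)
    }
    # xanthorhodopsin: two subgroup clusters from one archetype
    xr <- random_protein(length_aa)
    xr1a <- .set_positions(xr, .XR_I_RESIDUES)
    xr1b <- .set_positions(as.character(mutate_to_identity(xr1a, 0.85)),
                           .XR_I_RESIDUES)
    xr2arch <- .set_positions(as.character(mutate_to_identity(xr, 0.60)),
                              .XR_II_RESIDUES)
    xr2a <- .set_positions(as.character(mutate_to_identity(xr2arch, 0.88)),
                           .XR_II_RESIDUES)
    xr2b <- .set_positions(as.character(mutate_to_identity(xr2arch, 0.85)),
                           .XR_II_RESIDUES)
    push("XR1_a", xr1a, "xanthorhodopsin", "I")
    push("XR1_b", xr1b, "xanthorhodopsin", "I")
    push("XR2_a", xr2a, "xanthorhodopsin", "II")
    push("XR2_b", xr2b, "xanthorhodopsin", "II")
    for (g in setdiff(RHODOPSIN_GROUPS, "xanthorhodopsin")) {
      arch <- random_protein(length_aa)
      push(paste0(g, "_a"), arch, g)
      push(paste0(g, "_b"), as.character(mutate_to_identity(arch, 0.85)), g)
    }
    rhodopsin_refs(unlist(seqs), grp, sg)
  })
}

#' Parameters for a synthetic metagenome
#'
#' @param n_reads total reads (must exceed 100,000 for the screen to accept
#'   the sample)
#' @param regime "454" (right-skewed 100-400 bp, mean < 150) or "sanger"
#'   (700-1000 bp)
#' @param planted data.frame (group, subgroup, count) of rhodopsin
#'   fragments to plant, or NULL for none
#' @param fragment_identity protein identity of planted fragments to their
#'   source reference
#' @param background_gc GC of the i.i.d. background reads
#' @param habitat habitat tag
#' @param seed RNG seed
#' @return a `metagenome_params`
#' @export
metagenome_params <- function(n_reads = 105000, regime = c("454", "sanger"),
                              planted = NULL, fragment_identity = 0.90,
                              background_gc = 0.45, habitat = "marine",
                              seed = 1) {
  regime <- match.arg(regime)
  if (!is.null(planted)) {
    stopifnot(all(c("group", "count") %in% names(planted)),
              sum(planted$count) <= n_reads)
  }
  structure(as.list(environment()), class = "metagenome_params")
}

.draw_read_lengths <- function(n, regime) {
  if (regime == "454") {
    # right-skewed: most mass 100-150 bp, tail to 400, mean ~120
    len <- round(100 + stats::rgamma(n, shape = 1.2, scale = 18))
    pmin(pmax(len, 100L), 400L)
  } else {
    round(stats::runif(n, 700, 1000))
  }
}

#' Simulate a metagenome sample with planted rhodopsin fragments
#'
#' Background reads are i.i.d. nucleotides at the configured GC; planted
#' reads are random-position fragments (random strand) of back-translated,
#' optionally diverged copies of the labelled reference rhodopsins.
#'
#' @param params a [metagenome_params()]
#' @param refs a [rhodopsin_refs()]
#' @return list(sample = [metagenome_sample()], truth = data.frame
#'   (read_id, group, subgroup))
#' @export
simulate_metagenome <- function(params, refs) {
  stopifnot(inherits(params, "metagenome_params"),
            inherits(refs, "rhodopsin_refs"))
  .local_seed(params$seed + 2000L, {
    n <- params$n_reads
    lens <- .draw_read_lengths(n, params$regime)
    # background in one draw, then split
    big <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE,
                  prob = c((1 - params$background_gc) / 2,
                           params$background_gc / 2,
                           params$background_gc / 2,
                           (1 - params$background_gc) / 2))
    bigstr <- cc(big)
    ends <- cumsum(lens)
    reads <- substring(bigstr, ends - lens + 1, ends)
    names(reads) <- sprintf("read%07d", seq_len(n))
    truth <- data.frame(read_id = character(), group = character(),
                        subgroup = character(), stringsAsFactors = FALSE)
    if (!is.null(params$planted) && nrow(params$planted)) {
      slots <- sample(n, sum(params$planted$count))
      si <- 1L
      for (k in seq_len(nrow(params$planted))) {
        g <- params$planted$group[k]
        s2 <- if ("subgroup" %in% names(params$planted))
          params$planted$subgroup[k] else NA_character_
        pool <- which(refs$group == g &
                        (is.na(s2) | (!is.na(refs$subgroup) & refs$subgroup == s2)))
        if (length(pool) == 0) stopf("no reference for planted group %s", g)
        for (cp in seq_len(params$planted$count[k])) {
          ridx <- pool[1 + (cp - 1) %% length(pool)]
          aa <- as.character(mutate_to_identity(refs$seqs[[ridx]],
                                                params$fragment_identity))
          gene <- paste0(back_translate(aa), "TAA")
          want <- lens[slots[si]]
          flen <- min(want, nchar(gene))
          at <- sample(nchar(gene) - flen + 1, 1)
          frag <- substr(gene, at, at + flen - 1)
          if (stats::runif(1) < 0.5) frag <- revcomp(frag)
          reads[slots[si]] <- frag
          truth <- rbind(truth, data.frame(
            read_id = names(reads)[slots[si]], group = g, subgroup = s2,
            stringsAsFactors = FALSE))
          si <- si + 1L
        }
      }
    }
    smp <- metagenome_sample(reads, total_reads = n,
                                mean_read_length = mean(nchar(reads)),
                                habitat = params$habitat)
    list(sample = smp, truth = truth)
  })
}

#' Write a sample sheet for a set of metagenome samples
#' @param samples named list of `metagenome_sample`s
#' @param read_files character vector of read FASTA paths (same order)
#' @param path output TSV
#' @return invisibly, `path`
#' @export
write_sample_sheet <- function(samples, read_files, path) {
  df <- data.frame(
    sample_id = names(samples),
    read_file = read_files,
    total_reads = vapply(samples, function(s) s$total_reads, numeric(1)),
    mean_read_length = vapply(samples, function(s) s$mean_read_length, numeric(1)),
    habitat = vapply(samples, function(s) s$habitat, character(1)),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}
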