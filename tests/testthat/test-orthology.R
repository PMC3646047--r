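# Bidirectional best-hit orthology, pan-genome partitioning, MLSA markers
# and neighbor-joining.

test_that("best hits of identical proteomes are the twins, and match the
           exhaustive argmax oracle", {
  set.seed(21)
  pa <- setNames(replicate(20, rnd_protein(sample(60:120, 1))),
                 sprintf("a%02d", 1:20))
  bh <- best_hits(pa, setNames(pa, names(pa)))
  expect_equal(bh$query, bh$subject)
  # oracle: explicit all-vs-all argmax with the same scoring surface
  pb <- setNames(replicate(15, rnd_protein(sample(60:120, 1))),
                 sprintf("b%02d", 1:15))
  pb[1:5] <- vapply(pa[1:5], function(s)
    as.character(mutate_to_identity(s, 0.7)), "")
  sch <- scoring_scheme("protein")
  bh2 <- best_hits(pa, pb)
  for (q in bh2$query) {
    scores <- vapply(pb, function(s) local_align(pa[[q]], s, sch)$score,
                     numeric(1))
    expect_equal(unname(scores[bh2$subject[bh2$query == q]]), max(scores))
  }
  expect_error(best_hits(pa, character(0)), "empty")
})

test_that("hits above the significance cutoff are discarded", {
  set.seed(22)
  pa <- setNames(replicate(4, rnd_protein(80)), paste0("a", 1:4))
  pb <- setNames(replicate(4, rnd_protein(80)), paste0("b", 1:4))
  # unrelated random proteins: no hit reaches e < 1e-10
  bh <- best_hits(pa, pb)
  expect_equal(nrow(bh), 0)
  # with a permissive cutoff the same comparison does produce hits
  bh2 <- best_hits(pa, pb, orthology_config(evalue_cutoff = 10))
  expect_gt(nrow(bh2), 0)
})

test_that("bbh orthologs recover planted pairs and apply both identity bands", {
  sim <- simulate_genome_pair(genome_pair_params(
    n_genes = 30, identity_levels = c(0.45, 0.75), identity_props = c(0.5, 0.5),
    n_te_families = 1, te_copies = 1, seed = 31))
  orth <- bbh_orthologs(extract_proteome(sim$genome_a),
                        extract_proteome(sim$genome_b))
  tr <- sim$truth$orthologs
  tr <- tr[tr$both_coding, ]
  got <- setNames(orth$class, orth$query)[tr$locus_a]
  expect_true(all(got[tr$target_identity == 0.45] == "ortholog"))
  expect_true(all(got[tr$target_identity == 0.75] == "high_confidence"))
  # symmetry: the reverse comparison returns the same pair set
  orth_rev <- bbh_orthologs(extract_proteome(sim$genome_b),
                            extract_proteome(sim$genome_a))
  expect_setequal(paste(orth$query, orth$subject),
                  paste(orth_rev$subject, orth_rev$query))
})

test_that("pairs below 30% global identity are excluded despite reciprocity,
           and raising the cutoff never increases the count", {
  sim <- simulate_genome_pair(genome_pair_params(
    n_genes = 24, identity_levels = c(0.25, 0.45), identity_props = c(0.5, 0.5),
    n_te_families = 1, te_copies = 1, seed = 37))
  pa <- extract_proteome(sim$genome_a)
  pb <- extract_proteome(sim$genome_b)
  orth <- bbh_orthologs(pa, pb)
  tr <- sim$truth$orthologs[sim$truth$orthologs$both_coding, ]
  low <- tr$locus_a[tr$target_identity == 0.25]
  expect_false(any(low %in% orth$query))
  for (cut in c(0.30, 0.50, 0.70)) {
    n0 <- nrow(bbh_orthologs(pa, pb, orthology_config(identity_cutoff = cut)))
    n1 <- nrow(bbh_orthologs(pa, pb, orthology_config(identity_cutoff = cut + 0.1)))
    expect_lte(n1, n0)
  }
})

test_that("identical proteomes give all-high-confidence identity-1 pairs", {
  set.seed(41)
  pa <- setNames(replicate(8, rnd_protein(90)), sprintf("g%02d", 1:8))
  orth <- bbh_orthologs(pa, pa)
  expect_equal(nrow(orth), 8)
  expect_true(all(orth$identity == 1))
  expect_true(all(orth$class == "high_confidence"))
})

test_that("pan-genome labels follow the planted ortholog structure", {
  set.seed(51)
  shared <- replicate(6, rnd_protein(100))  # in all three genomes
  pair_only <- replicate(3, rnd_protein(100)) # A and B only
  pa <- setNames(c(shared,
                   vapply(pair_only, function(s) as.character(mutate_to_identity(s, 0.8)), ""),
                   replicate(2, rnd_protein(100))),
                 sprintf("a%02d", 1:11))
  pb <- setNames(c(vapply(shared, function(s) as.character(mutate_to_identity(s, 0.8)), ""),
                   pair_only,
                   replicate(3, rnd_protein(100))),
                 sprintf("b%02d", 1:12))
  pc <- setNames(c(vapply(shared, function(s) as.character(mutate_to_identity(s, 0.75)), ""),
                   replicate(2, rnd_protein(100))),
                 sprintf("c%02d", 1:8))
  pg <- pan_genome(list(A = pa, B = pb, C = pc), pair = c("A", "B"))
  ca <- pg$counts[pg$counts$genome_id == "A", ]
  expect_equal(ca$shared, 6)
  expect_equal(ca$exclusive, 3)
  expect_equal(ca$unique, 2)
  # fractions partition each proteome
  fr <- pg$fractions
  expect_equal(fr$shared + fr$exclusive + fr$unique, rep(1, 3))
  # two disjoint proteomes are 100% unique
  set.seed(52)
  px <- setNames(replicate(5, rnd_protein(80)), paste0("x", 1:5))
  py <- setNames(replicate(5, rnd_protein(80)), paste0("y", 1:5))
  pg2 <- pan_genome(list(X = px, Y = py))
  expect_true(all(pg2$genes$label == "unique"))
})

test_that("single-copy marker selection enforces presence and no paralogs", {
  set.seed(61)
  base <- replicate(5, rnd_protein(80))
  mk <- function(lv) setNames(vapply(base, function(s)
    as.character(mutate_to_identity(s, lv)), ""), sprintf("m%02d", 1:5))
  gen <- list(A = setNames(base, sprintf("m%02d", 1:5)), B = mk(0.85), C = mk(0.8))
  mks <- single_copy_markers(gen)
  expect_equal(length(mks), 5)
  # duplicating one gene in one genome removes that marker everywhere
  gen_dup <- gen
  gen_dup$B <- c(gen_dup$B, m99 = unname(gen_dup$B[["m01"]]))
  mks_dup <- single_copy_markers(gen_dup)
  expect_equal(length(mks_dup), 4)
  expect_false("m01" %in% names(mks_dup))
  # removing a gene from one genome removes the marker too
  gen_del <- gen
  gen_del$C <- gen_del$C[-2]
  mks_del <- single_copy_markers(gen_del)
  expect_false("m02" %in% names(mks_del))
  # no markers -> empty with warning
  set.seed(62)
  expect_warning(
    none <- single_copy_markers(list(
      P = setNames(replicate(3, rnd_protein(70)), paste0("p", 1:3)),
      Q = setNames(replicate(3, rnd_protein(70)), paste0("q", 1:3)))),
    "no single-copy markers")
  expect_equal(length(none), 0)
})

test_that("MLSA concatenation removes gapped columns and preserves the
           length-weighted distance identity on gap-free data", {
  set.seed(71)
  # substitution-only divergence keeps pairwise alignments gap-free
  base <- lapply(c(60, 90, 120), rnd_protein)
  markers <- lapply(seq_along(base), function(i) {
    m <- c(A = base[[i]],
           B = as.character(mutate_to_identity(base[[i]], 0.8)),
           C = as.character(mutate_to_identity(base[[i]], 0.7)))
    m
  })
  names(markers) <- sprintf("mk%d", seq_along(markers))
  al <- mlsa_concat(markers)
  expect_equal(unname(nchar(al$alignment[1])), 60 + 90 + 120)
  expect_equal(al$removed_columns, 0)
  d_concat <- p_distance(al)
  # length-weighted average of per-marker p-distances
  dm <- lapply(markers, function(m) p_distance(m))
  lens <- vapply(markers, function(m) nchar(m[[1]]), numeric(1))
  d_avg <- Reduce(`+`, Map(`*`, dm, lens)) / sum(lens)
  expect_equal(d_concat, d_avg[rownames(d_concat), colnames(d_concat)],
               tolerance = 1e-12)
})

test_that("gapped columns are removed exactly", {
  m <- list(mk1 = c(A = "MKLVFF", B = "MKLVFF", C = "MKVFF"))
  al <- mlsa_concat(m)
  # the alignment of C forces one gap column; all rows must drop it
  expect_equal(unique(nchar(al$alignment)), 5L)
  expect_equal(al$removed_columns, 1L)
  expect_false(any(grepl("-", al$alignment, fixed = TRUE)))
  # every column gapped in some row -> error
  m2 <- list(mk1 = c(A = "MKRW", B = "MK", C = "RW"))
  expect_error(mlsa_concat(m2), "no columns left")
})

test_that("neighbor-joining solves the 3-taxon case in closed form and is
           exact on additive matrices", {
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 5 - 6) / 2)
  expect_equal(bl[["b"]], (3 + 6 - 5) / 2)
  expect_equal(bl[["c"]], (5 + 6 - 3) / 2)
  # additive 4-taxon matrix from tree ((A:1,B:2):1.5,(C:3,D:4))
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  term <- c(A = 1, B = 2, C = 3, D = 4)
  for (i in LETTERS[1:4]) for (j in LETTERS[1:4]) {
    if (i == j) next
    inner <- if ((i %in% c("A", "B")) != (j %in% c("A", "B"))) 1.5 else 0
    d4[i, j] <- term[i] + term[j] + inner
  }
  tr4 <- nj_tree(d4)
  expect_true(ape::is.monophyletic(tr4, c("A", "B")))
  pd <- ape::cophenetic.phylo(tr4)
  expect_equal(pd[rownames(d4), colnames(d4)], d4, tolerance = 1e-10)
  # permutation invariance up to relabeling
  perm <- c("C", "A", "D", "B")
  tr4p <- nj_tree(d4[perm, perm])
  expect_equal(ape::cophenetic.phylo(tr4p)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-10)
  # degenerate inputs
  expect_error(nj_tree(d4[1:2, 1:2]), "at least 3")
  dbad <- d4
  dbad[1, 2] <- -1
  expect_error(nj_tree(dbad), "symmetric")
})
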