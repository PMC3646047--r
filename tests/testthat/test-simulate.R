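# Synthetic-data generators: seeding contract, truth-table consistency,
# and identity control.

test_that("mutate_to_identity hits its target and respects the seeding
           contract", {
  set.seed(1)
  p <- rnd_protein(300)
  expect_identical(as.character(mutate_to_identity(p, 1.0)), p)
  m <- mutate_to_identity(p, 0.45, seed = 3)
  realized <- global_align(p, as.character(m))$identity_fraction
  expect_gte(realized, 0.43)
  expect_lte(realized, 0.47)
  expect_equal(attr(m, "realized_identity"), realized)
  # same seed -> same output; different seeds -> different, equally close
  expect_identical(as.character(mutate_to_identity(p, 0.45, seed = 3)),
                   as.character(m))
  m2 <- mutate_to_identity(p, 0.45, seed = 4)
  expect_false(identical(as.character(m2), as.character(m)))
  r2 <- global_align(p, as.character(m2))$identity_fraction
  expect_lte(abs(r2 - 0.45), 0.02)
  # indels allowed, still within tolerance
  mi <- mutate_to_identity(p, 0.6, seed = 5, indel_rate = 0.05)
  expect_lte(abs(attr(mi, "realized_identity") - 0.6), 0.02)
  expect_error(mutate_to_identity(p, 0), "target")
})

test_that("genome-pair generation is byte-deterministic per seed", {
  pp <- genome_pair_params(n_genes = 15, n_islands = 1, island_n_genes = 3,
                           n_inversions = 1, pseudogene_frac = 0.1, seed = 5)
  s1 <- simulate_genome_pair(pp)
  s2 <- simulate_genome_pair(pp)
  expect_identical(s1$genome_a, s2$genome_a)
  expect_identical(s1$genome_b, s2$genome_b)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_genome_pair(genome_pair_params(n_genes = 15, n_islands = 1,
                                                island_n_genes = 3,
                                                n_inversions = 1,
                                                pseudogene_frac = 0.1,
                                                seed = 6))
  expect_false(identical(s1$genome_a, s3$genome_a))
  # emitted GenBank is byte-identical too
  f1 <- tempfile(); f2 <- tempfile()
  write_genbank(s1$genome_a, f1)
  write_genbank(s2$genome_a, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a zero-divergence zero-rearrangement pair has identical gene
           complements", {
  sim <- simulate_genome_pair(genome_pair_params(
    n_genes = 10, identity_levels = 1, identity_props = 1,
    n_te_families = 1, te_copies = 1, n_inversions = 0, seed = 8))
  pa <- extract_proteome(sim$genome_a)
  pb <- extract_proteome(sim$genome_b)
  core_a <- pa$sequence[grepl("^GA_\\d", pa$locus_tag)]
  core_b <- pb$sequence[grepl("^GB_\\d", pb$locus_tag)]
  expect_identical(core_a, core_b)
  expect_true(all(sim$truth$orthologs$realized_identity == 1))
})

test_that("the truth table is consistent with the emitted sequences", {
  sim <- simulate_genome_pair(genome_pair_params(
    n_genes = 20, identity_levels = c(0.45, 0.75), identity_props = c(.5, .5),
    n_te_families = 2, te_copies = 2, n_islands = 1, island_n_genes = 3,
    pseudogene_frac = 0.1, seed = 13))
  pa <- proteome_seqs(sim$genome_a)
  pb <- proteome_seqs(sim$genome_b)
  tr <- sim$truth$orthologs
  for (i in which(tr$both_coding)) {
    r <- global_align(pa[[tr$locus_a[i]]], pb[[tr$locus_b[i]]])$identity_fraction
    expect_equal(r, tr$realized_identity[i], tolerance = 1e-9)
    expect_lte(abs(r - tr$target_identity[i]), 0.03)
  }
  ft <- rbind(feature_table(sim$genome_a), feature_table(sim$genome_b))
  # TE truth rows point at annotated TE features of the right family
  for (i in seq_len(nrow(sim$truth$te))) {
    f <- ft[ft$locus_tag == sim$truth$te$locus_tag[i], ]
    expect_equal(f$te_family, sim$truth$te$family[i])
  }
  # island intervals lie inside the genome and contain island loci
  len_a <- genome_length(sim$genome_a)
  for (i in seq_len(nrow(sim$truth$islands))) {
    expect_gte(sim$truth$islands$start[i], 0)
    expect_lte(sim$truth$islands$end[i], len_a)
  }
  # pseudogene truth rows are annotated as pseudogenes
  for (i in seq_len(nrow(sim$truth$pseudogenes))) {
    f <- ft[ft$locus_tag == sim$truth$pseudogenes$locus_tag[i], ]
    expect_equal(f$kind, "pseudogene")
  }
  # all features inside replicon bounds (emission fuzz contract)
  expect_true(all(ft$start >= 0))
  expect_true(all(ft$end <= pmax(genome_length(sim$genome_a),
                                 genome_length(sim$genome_b))))
})

test_that("metagenome generation is deterministic, respects the planted
           labels and the read-length regimes", {
  refs <- simulate_rhodopsin_refs(seed = 2)
  pl <- data.frame(group = "xanthorhodopsin", subgroup = "II", count = 8)
  pp <- metagenome_params(n_reads = 3000, regime = "454", planted = pl, seed = 3)
  m1 <- simulate_metagenome(pp, refs)
  m2 <- simulate_metagenome(pp, refs)
  expect_identical(m1$sample$reads, m2$sample$reads)
  expect_identical(m1$truth, m2$truth)
  expect_equal(nrow(m1$truth), 8)
  expect_true(all(nchar(m1$sample$reads) >= 100))
  expect_true(all(nchar(m1$sample$reads) <= 400))
  expect_lte(m1$sample$mean_read_length, 150)
  # planted reads really are fragments of subgroup-II genes: best local
  # score against a subgroup-II reference beats every other group
  sch <- scoring_scheme("protein")
  fr <- six_frame_translate(m1$sample$reads[m1$truth$read_id])
  best_by_ref <- vapply(seq_along(refs$seqs), function(j)
    max(sw_score_batch(fr$aa[nchar(fr$aa) > 0], refs$seqs[[j]], sch)),
    numeric(1))
  expect_equal(refs$subgroup[which.max(best_by_ref)], "II")
  # sanger-like regime: long reads
  ms <- simulate_metagenome(metagenome_params(n_reads = 500, regime = "sanger",
                                              seed = 4), refs)
  expect_true(all(nchar(ms$sample$reads) >= 700))
  expect_gt(ms$sample$mean_read_length, 150)
  # over-planting is rejected
  expect_error(metagenome_params(n_reads = 5, planted = data.frame(
    group = "fungal", subgroup = NA, count = 10)), "count")
})

test_that("sample sheets round-trip the per-sample metadata", {
  refs <- simulate_rhodopsin_refs(seed = 2)
  m <- simulate_metagenome(metagenome_params(n_reads = 200, seed = 9), refs)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(m$sample$reads, fa, "dna")
  sheet <- tempfile(fileext = ".tsv")
  write_sample_sheet(list(s1 = m$sample), fa, sheet)
  df <- read.delim(sheet)
  expect_equal(df$total_reads, 200)
  expect_equal(df$mean_read_length, m$sample$mean_read_length)
  back <- read_fasta_dna(fa)
  expect_identical(back, m$sample$reads)
})
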