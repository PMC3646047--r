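# Two-stage rhodopsin screen: printed rules, classification, binding-site
# profiling and subgroup assignment.

refs <- simulate_rhodopsin_refs(seed = 1)
cfg <- screen_config()

test_that("the reference-set contract enforces two members per main group", {
  expect_error(rhodopsin_refs(c(x = "MAY"), "proteorhodopsin"), ">= 2")
  expect_error(rhodopsin_refs(c(x = "MAY", y = "MAW"),
                              c("proteorhodopsin", "mystery")), "unknown")
  tf <- tempfile(fileext = ".faa")
  write_rhodopsin_refs(refs, tf)
  refs2 <- read_rhodopsin_refs(tf)
  expect_identical(refs2$seqs, refs$seqs)
  expect_identical(refs2$group, refs$group)
  expect_identical(refs2$subgroup, refs$subgroup)
})

test_that("the read-length rule is a step function with 150 bp on the
           permissive side", {
  expect_equal(stage2_cutoff(120, cfg), 1e-10)
  expect_equal(stage2_cutoff(149, cfg), 1e-10)
  expect_equal(stage2_cutoff(150, cfg), 1e-10)
  expect_equal(stage2_cutoff(151, cfg), 1e-20)
  expect_equal(stage2_cutoff(300, cfg), 1e-20)
})

test_that("the coverage rule is the printed 60%-reference / 80%-query
           disjunction", {
  expect_false(passes_coverage(0.50, 0.70, cfg))
  expect_true(passes_coverage(0.60, 0.00, cfg))
  expect_true(passes_coverage(0.00, 0.80, cfg))
  expect_true(passes_coverage(0.59, 0.80, cfg))
  expect_false(passes_coverage(0.59, 0.79, cfg))
})

test_that("surveys at or below 100,000 reads are refused by stage 1", {
  small <- metagenome_sample(setNames(rnd_dna(120), "r1"), total_reads = 50000)
  expect_error(stage1_screen(small, refs, cfg), "100000")
  at_min <- metagenome_sample(setNames(rnd_dna(120), "r1"), total_reads = 100000)
  expect_error(stage1_screen(at_min, refs, cfg), "100000")
})

test_that("a candidate at 5e-12 passes the short-read cutoff but fails the
           long-read cutoff, applied through stage-2 filtering", {
  cand <- data.frame(read_id = "r1", read = 1L, frame = 1L, score = 100L,
                     evalue = 5e-12, stringsAsFactors = FALSE)
  s_short <- metagenome_sample(setNames(rnd_dna(120), "r1"),
                               total_reads = 2e5, mean_read_length = 120)
  s_long <- metagenome_sample(setNames(rnd_dna(120), "r1"),
                              total_reads = 2e5, mean_read_length = 300)
  expect_equal(stage2_cutoff(s_short$mean_read_length, cfg), 1e-10)
  expect_gt(5e-12 / stage2_cutoff(s_long$mean_read_length, cfg), 1)
  # the same candidate survives the cutoff filter only in the short sample
  surv_short <- cand$evalue <= stage2_cutoff(s_short$mean_read_length, cfg)
  surv_long <- cand$evalue <= stage2_cutoff(s_long$mean_read_length, cfg)
  expect_true(surv_short)
  expect_false(surv_long)
})

test_that("the end-to-end screen recovers planted fragments, rejects the
           background, and respects the stage ordering invariants", {
  planted <- data.frame(
    group = c("proteorhodopsin", "xanthorhodopsin", "xanthorhodopsin"),
    subgroup = c(NA, "I", "II"), count = c(60, 20, 40),
    stringsAsFactors = FALSE)
  mg <- simulate_metagenome(metagenome_params(
    n_reads = 101000, regime = "454", planted = planted, seed = 17), refs)
  expect_lte(mg$sample$mean_read_length, 150)
  res <- run_screen(mg$sample, refs, cfg)
  # stage 2 is a subset of stage 1
  expect_true(all(res$validated$read_id %in% res$candidates$read_id))
  # nearly all planted reads retained by stage 1
  expect_gte(sum(mg$truth$read_id %in% res$candidates$read_id), 119)
  # validated reads are planted reads, and recovery is essentially total
  expect_true(all(res$validated$read_id %in% mg$truth$read_id))
  expect_gte(nrow(res$validated), 0.95 * sum(planted$count))
  # group attribution matches the planted labels
  m <- merge(res$validated, mg$truth, by = "read_id")
  expect_gte(mean(m$group.x == m$group.y), 0.98)
  # profile arithmetic: per-mille normalization against total reads
  prof <- res$profile
  expect_equal(prof$total_per_mille,
               1000 * nrow(res$validated) / mg$sample$total_reads)
  expect_equal(sum(prof$by_group$count), nrow(res$validated))
  # loosening the stage-2 cutoff never decreases validated counts
  stricter <- screen_config(stage2_evalue_short = 1e-15)
  v2 <- stage2_validate(res$candidates, refs, mg$sample, stricter)
  expect_lte(nrow(v2), nrow(res$validated))
})

test_that("an empty sample produces an empty profile and zero abundances", {
  mg <- simulate_metagenome(metagenome_params(
    n_reads = 101000, regime = "454", planted = NULL, seed = 23), refs)
  res <- run_screen(mg$sample, refs, cfg)
  expect_equal(nrow(res$validated), 0)
  expect_equal(res$profile$total_count, 0)
  expect_true(all(res$profile$by_group$per_mille == 0))
})

test_that("doubling the survey size with no new hits halves every
           normalized abundance exactly", {
  v <- data.frame(read_id = paste0("r", 1:6),
                  group = c(rep("proteorhodopsin", 4), "xanthorhodopsin",
                            "xanthorhodopsin"),
                  subgroup = c(rep(NA, 4), "I", "II"), stringsAsFactors = FALSE)
  s1 <- metagenome_sample(setNames(rnd_dna(120), "r1"), total_reads = 3e5)
  s2 <- metagenome_sample(setNames(rnd_dna(120), "r1"), total_reads = 6e5)
  p1 <- classify_hits(v, s1)
  p2 <- classify_hits(v, s2)
  expect_equal(p2$by_group$per_mille, p1$by_group$per_mille / 2)
  expect_equal(p1$total_per_mille, 1000 * 6 / 3e5)
  # 150 hits in 300,000 reads -> 0.5 per mille
  v150 <- data.frame(read_id = paste0("r", 1:150), group = "proteorhodopsin",
                     subgroup = NA_character_, stringsAsFactors = FALSE)
  expect_equal(classify_hits(v150, s1)$total_per_mille, 0.5)
  # subgroup-II share of all validated rhodopsins
  expect_equal(p1$subgroup2_percent, 100 * 1 / 6)
})

test_that("binding-site profiling counts identities/similarities at the
           spec positions and applies the Gly156 rule", {
  spec <- binding_site_spec()
  ref1 <- refs$seqs[["XR1_a"]]
  self <- binding_site_profile(ref1, spec, ref1)
  expect_equal(self$identities, length(spec$positions))
  expect_equal(self$verdict, "possible")
  expect_false(self$partial)
  # engineered tryptophan at the 156-equivalent abolishes binding
  w156 <- ref1
  substr(w156, 156, 156) <- "W"
  expect_equal(binding_site_profile(w156, spec, ref1)$verdict, "abolished")
  # A and S at the key position still permit binding
  for (res in c("A", "S")) {
    v <- ref1
    substr(v, 156, 156) <- res
    expect_equal(binding_site_profile(v, spec, ref1)$verdict, "possible")
  }
  # subgroup II references: bulky W, degenerate helix-F slot
  p2 <- binding_site_profile(refs$seqs[["XR2_a"]], spec, ref1)
  expect_equal(p2$key_residue, "W")
  expect_equal(p2$verdict, "abolished")
  # constructed opsin matching at exactly 5 of 7 positions
  v5 <- ref1
  substr(v5, 194, 194) <- "W"
  substr(v5, 205, 205) <- "R"
  expect_equal(binding_site_profile(v5, spec, ref1)$identities,
               length(spec$positions) - 2)
  # spec outside the reference errors
  expect_error(binding_site_profile(ref1, binding_site_spec(c(156, 9999)),
                                    ref1), "shorter")
})

test_that("subgroup assignment uses nearest reference with an identity floor
           and a margin", {
  expect_equal(assign_subgroup(refs$seqs[["XR1_a"]], refs), "I")
  expect_equal(assign_subgroup(refs$seqs[["XR2_b"]], refs), "II")
  derived <- as.character(mutate_to_identity(refs$seqs[["XR2_a"]], 0.8,
                                             seed = 5))
  expect_equal(assign_subgroup(derived, refs), "II")
  set.seed(55)
  expect_equal(assign_subgroup(rnd_protein(240), refs), "unassigned")
})
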