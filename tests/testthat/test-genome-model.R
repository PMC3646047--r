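# Genome data model and GenBank flat-file I/O.

test_that("GenBank coordinates convert to the 0-based half-open convention", {
  gb <- c(
    "LOCUS       test 30 bp    DNA     linear   BCT",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..30",
    "     CDS             10..18",
    "                     /locus_tag=\"g1\"",
    "     CDS             complement(20..28)",
    "                     /locus_tag=\"g2\"",
    "                     /pseudo",
    "ORIGIN",
    "        1 atgaaatttg ggcccaaatt tggccctaaa",
    "//")
  tf <- tempfile(fileext = ".gbk")
  writeLines(gb, tf)
  g <- read_genbank(tf, genome_id = "toy", organism = "toy org")
  ft <- feature_table(g)
  f1 <- ft[ft$locus_tag == "g1", ]
  expect_equal(f1$start, 9L)
  expect_equal(f1$end, 18L)
  expect_equal(f1$strand, "+")
  expect_equal(f1$kind, "CDS")
  f2 <- ft[ft$locus_tag == "g2", ]
  expect_equal(f2$kind, "pseudogene")
  expect_equal(f2$strand, "-")
})

test_that("a record without a sequence block is a hard error", {
  tf <- tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       x 10 bp DNA linear", "//"), tf)
  expect_error(read_genbank(tf), "ORIGIN")
})

test_that("a malformed location names the offending locus", {
  gb <- c("LOCUS       bad 20 bp DNA linear",
          "FEATURES             Location/Qualifiers",
          "     CDS             10..blorp",
          "                     /locus_tag=\"broken\"",
          "ORIGIN",
          "        1 atgaaatttg ggcccaaatt",
          "//")
  tf <- tempfile(fileext = ".gbk")
  writeLines(gb, tf)
  expect_error(read_genbank(tf), "broken")
})

test_that("generator-emitted GenBank round-trips features and sequence", {
  sim <- simulate_genome_pair(genome_pair_params(
    n_genes = 12, n_islands = 1, island_n_genes = 3,
    pseudogene_frac = 0.1, seed = 42))
  for (g in list(sim$genome_a, sim$genome_b)) {
    tf <- tempfile(fileext = ".gbk")
    write_genbank(g, tf)
    g2 <- read_genbank(tf, genome_id = g$genome_id, organism = g$organism)
    expect_identical(g2$replicons[[1]]$sequence, g$replicons[[1]]$sequence)
    expect_identical(feature_table(g2), feature_table(g))
    expect_identical(g2$replicons[[1]]$topology, g$replicons[[1]]$topology)
  }
})

test_that("proteome extraction excludes pseudogenes and translates - strands", {
  sim <- simulate_genome_pair(genome_pair_params(
    n_genes = 20, pseudogene_frac = 0.2, seed = 9))
  g <- sim$genome_a
  ft <- feature_table(g)
  prot <- extract_proteome(g)
  expect_equal(nrow(prot), sum(ft$kind == "CDS"))
  expect_false(any(prot$locus_tag %in%
                     sim$truth$pseudogenes$locus_tag[sim$truth$pseudogenes$genome_id == "A"]))
  # a minus-strand CDS translates through the reverse complement
  minus <- ft[ft$kind == "CDS" & ft$strand == "-", ][1, ]
  r <- g$replicons[[minus$replicon]]
  span <- substr(r$sequence, minus$start + 1, minus$end)
  aa <- genoplast:::translate_cds(genoplast::revcomp(span))
  expect_equal(sub("\\*$", "", aa),
               prot$sequence[prot$locus_tag == minus$locus_tag])
  # no internal stops in any extracted protein
  expect_false(any(grepl("*", prot$sequence, fixed = TRUE)))
})

test_that("an internal stop in a non-pseudo CDS is skipped with a warning", {
  r <- replicon("c1", paste0("ATG", "TAA", "AAATAA"), "linear", "chromosome",
                list(feature("CDS", 0, 12, "+", "bad1")))
  g <- annotated_genome("x", "org", list(r))
  expect_warning(p <- extract_proteome(g), "bad1")
  expect_equal(nrow(p), 0)
  expect_equal(attr(p, "skipped"), 1L)
})

test_that("gc_content follows the stated conventions", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("GGCCNNNN"), 100) # N excluded from denominator
  expect_error(gc_content("NNN"), "undefined")
  # invariance under reverse complement and concatenation order
  set.seed(12)
  s1 <- rnd_dna(500, 0.6)
  s2 <- rnd_dna(300, 0.4)
  g12 <- annotated_genome("g", "o", list(
    replicon("r1", s1, "linear", "chromosome"),
    replicon("r2", s2, "linear", "chromosome")))
  g21 <- annotated_genome("g", "o", list(
    replicon("r2", s2, "linear", "chromosome"),
    replicon("r1", s1, "linear", "chromosome")))
  expect_equal(gc_content(g12), gc_content(g21))
  expect_equal(gc_content(s1), gc_content(revcomp_chr(s1)))
  # reporting rounds half away from zero
  expect_equal(gc_content(paste0(strrep("G", 111), strrep("A", 89)),
                          rounded = TRUE), 56) # 55.5 -> 56
})

test_that("genome summary counts follow the generator truth", {
  sim <- simulate_genome_pair(genome_pair_params(
    n_genes = 25, pseudogene_frac = 0.12, n_te_families = 2, te_copies = 3,
    seed = 4))
  g <- sim$genome_a
  cen <- te_census(g, sim$te_library)
  s <- summarize_genome(g, cen)
  n_ps <- sum(sim$truth$pseudogenes$genome_id == "A")
  n_te <- sum(sim$truth$te$genome_id == "A")
  expect_equal(s$n_pseudogenes, n_ps)
  expect_equal(s$n_protein_coding, 25 - n_ps + n_te)
  expect_equal(s$n_rna_genes, 6)
  expect_equal(s$n_te_genes, n_te)
  expect_equal(s$te_per_mb, n_te / (genome_length(g) / 1e6))
  # proteome size + pseudogene count = CDS-like features
  ft <- feature_table(g)
  expect_equal(nrow(extract_proteome(g)) + s$n_pseudogenes,
               sum(ft$kind %in% c("CDS", "pseudogene")))
})

test_that("an empty-feature genome summarizes to zero counts", {
  g <- annotated_genome("e", "o", list(
    replicon("r", rnd_dna(2000), "linear", "chromosome")))
  s <- summarize_genome(g)
  expect_equal(s$n_protein_coding, 0)
  expect_equal(s$n_pseudogenes, 0)
  expect_equal(s$n_rna_genes, 0)
  expect_equal(s$te_per_mb, 0)
})
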