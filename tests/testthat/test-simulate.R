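test_that("generators are bit-identical for identical seeds and configs", {
  p1 <- make_cytotype_pair(small_cfg(seed = 3))
  p2 <- make_cytotype_pair(small_cfg(seed = 3))
  expect_identical(p1$type1$sequence, p2$type1$sequence)
  expect_identical(p1$type2$sequence, p2$type2$sequence)
  expect_identical(as.data.frame(p1$truth$variants),
                   as.data.frame(p2$truth$variants))
  expect_identical(p1$truth$inversion, p2$truth$inversion)
  pop1 <- simulate_population(p1)
  pop2 <- simulate_population(p2)
  expect_identical(pop1$alignment$seqs, pop2$alignment$seqs)
  b1 <- simulate_basecounts(p1$truth$loci, 0.1, small_cfg(seed = 3), seed = 3)
  b2 <- simulate_basecounts(p2$truth$loci, 0.1, small_cfg(seed = 3), seed = 3)
  expect_identical(b1$data, b2$data)
  expect_identical(b1$qual_fail, b2$qual_fail)
  p3 <- make_cytotype_pair(small_cfg(seed = 4))
  expect_false(identical(p1$type1$sequence, p3$type1$sequence))
})

test_that("a null config produces identical genomes", {
  pair <- make_cytotype_pair(small_cfg(seed = 5, n_diag_snps = 0L,
                                       n_diag_indels = 0L, inversion_len = 0L))
  expect_identical(pair$type1$sequence, pair$type2$sequence)
  expect_equal(nrow(pair$truth$variants), 0L)
  expect_null(pair$truth$inversion)
})

test_that("implanted architecture is recovered by structure detection", {
  cfg <- small_cfg(seed = 9)
  pair <- make_cytotype_pair(cfg)
  qs <- detect_quadripartite(pair$type1, min_ir_len = 4000)
  expect_identical(qs$lengths[["ir"]], cfg$ir_len)
  expect_identical(qs$lengths[["ssc"]], cfg$ssc_len)
  expect_identical(qs$lengths[["lsc"]],
                   cfg$genome_len - cfg$ssc_len - 2L * cfg$ir_len)
})

test_that("truth sets respect their own invariants", {
  pair <- make_cytotype_pair(small_cfg(seed = 15))
  v <- as.data.frame(pair$truth$variants)
  expect_true(all(diff(v$pos) >= 2L))
  inv <- pair$truth$inversion
  expect_false(any(v$pos >= inv[1] & v$pos <= inv[2]))
  expect_false(any(pair$truth$loci$pos >= inv[1] & pair$truth$loci$pos <= inv[2]))
  ## the second genome really differs from the first by the truth set
  rebuilt <- apply_variants(apply_inversion(pair$type1$sequence, inv[1], inv[2]),
                            pair$truth$variants)
  expect_identical(rebuilt, pair$type2$sequence)
})

test_that("population realizes its programmed haplotype structure", {
  pair <- make_cytotype_pair(small_cfg(seed = 7))
  pop <- simulate_population(pair)
  expect_equal(nrow(pop$samples), 43L)
  expect_equal(sum(pop$samples$cytotype == "Type 2"), 7L)
  ht <- build_haplotype_table(pop$truth$variant_sets)
  expect_equal(ht$n_haplotypes, 15L)
  ## haplotype ids group exactly as programmed
  expect_equal(unname(vapply(split(ht$haplotype, pop$truth$haplotype),
                             function(x) length(unique(x)), 1L)),
               rep(1L, 15L))
})

test_that("a single-haplotype population is monomorphic", {
  pair <- make_cytotype_pair(small_cfg(seed = 7))
  spec <- structure(list(haplotypes = list(list(n = 5L, cytotype = "Type 1",
                                                variants = integer())),
                         n_subgroup_snps = 0L, n_subgroup_indels = 0L),
                    class = "population_spec")
  pop <- simulate_population(pair, spec)
  prof <- sliding_window_pi(pop$alignment, window = 2000, step = 1000)
  expect_true(all(prof$pi == 0))
  expect_equal(pop$expected_pi, 0)
})

test_that("window diversity peaks inside the divergent (inversion) region", {
  pair <- make_cytotype_pair(small_cfg(seed = 7))
  pop <- simulate_population(pair)
  ## drop the mask so the structural difference shows as a diversity peak
  m <- alignment_matrix(pop$alignment$seqs)
  prof <- sliding_window_pi(m, window = 1200, step = 400)
  peak <- which.max(prof$pi)
  inv <- pop$alignment$excluded
  expect_true(prof$start[peak] <= inv[2] && prof$end[peak] >= inv[1])
})

test_that("base-count simulation respects its moment structure", {
  pair <- make_cytotype_pair(small_cfg(seed = 7))
  loci <- pair$truth$loci
  cfg <- small_cfg(depth = 4000L, qual_fail_rate = 0)
  prof <- simulate_basecounts(loci, 0, small_cfg(depth = 4000L, error_rate = 0,
                                                 qual_fail_rate = 0), seed = 2)
  minor <- plastotyper:::counts_at(prof$data, loci$allele_b)
  expect_true(all(minor == 0))
  expect_true(all(prof$data$depth == 4000L))
  expect_error(simulate_basecounts(loci, 0.1, small_cfg(depth = 0L)), "depth")
})
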