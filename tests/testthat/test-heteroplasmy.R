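## shared small fixtures: one scaled-down diagnostic locus set
het_pair <- make_cytotype_pair(small_cfg(seed = 7))
het_loci <- het_pair$truth$loci

test_that("quality filtering matches an independent recount", {
  cfg <- small_cfg(depth = 400L, qual_fail_rate = 0.1)
  prof <- simulate_basecounts(het_loci, 0.1, cfg, seed = 5)
  filt <- filter_basecounts(prof)
  ## oracle: subtract failing reads column-wise, then zero single-strand
  ## alleles, independently of the package's implementation
  d <- prof$data; q <- prof$qual_fail
  for (al in c("A", "C", "G", "T", "ins", "del")) {
    fc <- d[[paste0(al, "_f")]] - q[[paste0(al, "_f")]]
    rc <- d[[paste0(al, "_r")]] - q[[paste0(al, "_r")]]
    drop <- (fc == 0 & rc > 0) | (rc == 0 & fc > 0)
    fc[drop] <- 0L; rc[drop] <- 0L
    expect_equal(filt$data[[paste0(al, "_f")]], fc)
    expect_equal(filt$data[[paste0(al, "_r")]], rc)
  }
  expect_equal(filt$data$depth,
               rowSums(filt$data[, plastotyper:::BC_DEPTH_COLS]))
  expect_null(filt$qual_fail)
})

test_that("all-passing both-strand counts pass the filter unchanged", {
  ## no quality failures and no error alleles: at f = 0.2 both cytotype
  ## alleles are deeply covered on both strands, so nothing is removed
  cfg <- small_cfg(depth = 1000L, qual_fail_rate = 0, error_rate = 0)
  prof <- simulate_basecounts(het_loci, 0.2, cfg, seed = 6)
  filt <- filter_basecounts(prof)
  expect_equal(filt$data, prof$data)
})

test_that("an allele observed on a single strand is removed", {
  d <- data.frame(pos = 10L, ref = "A",
                  A_f = 50L, A_r = 48L, C_f = 3L, C_r = 0L,
                  G_f = 0L, G_r = 0L, T_f = 0L, T_r = 0L,
                  ins_f = 0L, ins_r = 0L, del_f = 0L, del_r = 0L,
                  depth = 101L)
  filt <- filter_basecounts(base_count_profile("s", d))
  expect_equal(filt$data$C_f, 0L)
  expect_equal(filt$data$depth, 98L)
})

test_that("major-type classification handles pure and mixed profiles", {
  cfg <- small_cfg(depth = 2000L)
  pure <- filter_basecounts(simulate_basecounts(het_loci, 0, cfg, seed = 11))
  expect_identical(classify_major_type(pure, het_loci), "Type 1")
  mix98_2 <- filter_basecounts(simulate_basecounts(het_loci, 0.02, cfg, seed = 12))
  expect_identical(classify_major_type(mix98_2, het_loci), "Type 1")
  mix2_98 <- filter_basecounts(simulate_basecounts(het_loci, 0.02, cfg,
                                                   seed = 13, major = "b"))
  expect_identical(classify_major_type(mix2_98, het_loci), "Type 2")
  few <- pure
  few$data <- few$data[1:5, ]
  expect_error(classify_major_type(few, het_loci), "at least")
})

test_that("an error-free pure profile yields zero minor fraction", {
  cfg <- small_cfg(depth = 2000L, error_rate = 0, qual_fail_rate = 0)
  prof <- filter_basecounts(simulate_basecounts(het_loci, 0, cfg, seed = 21))
  call <- estimate_minor_fraction(prof, het_loci)
  expect_equal(call$minor_fraction, 0)
  expect_equal(call$minor_fraction_mean, 0)
  expect_identical(call$verdict, "below_cutoff")
})

test_that("seeded mixtures are recovered at their stated tolerances", {
  cfg8 <- small_cfg(depth = 8000L)
  call02 <- estimate_minor_fraction(
    filter_basecounts(simulate_basecounts(het_loci, 0.02, cfg8, seed = 31)),
    het_loci)
  expect_lt(abs(call02$minor_fraction - 0.02), 0.005)
  expect_identical(call02$verdict, "heteroplasmy")

  cfg4 <- small_cfg(depth = 4000L)
  call11 <- estimate_minor_fraction(
    filter_basecounts(simulate_basecounts(het_loci, 0.11, cfg4, seed = 32)),
    het_loci)
  expect_lt(abs(call11$minor_fraction - 0.11), 0.01)
  expect_identical(call11$verdict, "heteroplasmy")
})

test_that("swapping the type labels leaves fraction and verdict unchanged", {
  cfg <- small_cfg(depth = 8000L)
  prof_a <- filter_basecounts(simulate_basecounts(het_loci, 0.05, cfg, seed = 41))
  prof_b <- filter_basecounts(simulate_basecounts(het_loci, 0.05, cfg,
                                                  seed = 41, major = "b"))
  call_a <- estimate_minor_fraction(prof_a, het_loci)
  call_b <- estimate_minor_fraction(prof_b, het_loci)
  expect_identical(call_a$major_type, "Type 1")
  expect_identical(call_b$major_type, "Type 2")
  expect_identical(call_b$minor_type, "Type 1")
  expect_equal(call_a$minor_fraction, call_b$minor_fraction, tolerance = 0.01)
  expect_identical(call_a$verdict, call_b$verdict)
})

test_that("the depth-ratio guard separates heteroplasmy from inserts", {
  cfg <- small_cfg(depth = 8000L)
  call <- estimate_minor_fraction(
    filter_basecounts(simulate_basecounts(het_loci, 0.05, cfg, seed = 51)),
    het_loci)
  ## organellar-scale minor depth (~400x) over ~45x nuclear: ratio ~ 9
  call$minor_mean_depth <- 450; call$nuclear_depth <- 45
  expect_identical(numt_guard(call)$verdict, "heteroplasmy")
  ## insert-scale minor depth: ambiguous
  call$minor_mean_depth <- 40
  expect_identical(numt_guard(call)$verdict, "ambiguous")
  ## a below-cutoff call stays below cutoff whatever the ratio
  cfg0 <- small_cfg(depth = 8000L, error_rate = 0, qual_fail_rate = 0)
  call0 <- estimate_minor_fraction(
    filter_basecounts(simulate_basecounts(het_loci, 0, cfg0, seed = 52)),
    het_loci)
  expect_identical(numt_guard(call0)$verdict, "below_cutoff")
})

test_that("masked organellar-insert loci are excluded from the estimate", {
  cfg <- small_cfg(depth = 2000L)
  numt_at <- het_loci$pos[c(2, 5)]
  prof <- filter_basecounts(simulate_basecounts(het_loci, 0, cfg, seed = 61,
                                                numt_loci = numt_at))
  hcfg <- heteroplasmy_config(mt_insert_mask = cbind(numt_at, numt_at))
  call <- estimate_minor_fraction(prof, het_loci, hcfg,
                                  major_type = "Type 1")
  expect_equal(call$n_usable_loci, nrow(het_loci) - 2L)
  expect_false(any(numt_at %in% call$per_locus$pos))
})

test_that("per-locus minor counts match the moment oracle", {
  cfg <- small_cfg(depth = 8000L, qual_fail_rate = 0)
  f <- 0.05; e <- cfg$error_rate
  prof <- filter_basecounts(simulate_basecounts(het_loci, f, cfg, seed = 71))
  call <- estimate_minor_fraction(prof, het_loci, major_type = "Type 1")
  expected <- f * (1 - e) + (1 - f) * e / 3
  se <- sqrt(expected * (1 - expected) / cfg$depth / nrow(het_loci))
  expect_lt(abs(mean(call$per_locus$minor_freq) - expected), 3 * se)
})

test_that("estimator bias shrinks with depth", {
  f <- 0.03
  bias_at <- function(depth) {
    errs <- vapply(1:12, function(s) {
      cfg <- small_cfg(depth = depth)
      call <- estimate_minor_fraction(
        filter_basecounts(simulate_basecounts(het_loci, f, cfg, seed = 700 + s)),
        het_loci, major_type = "Type 1")
      abs(call$minor_fraction - f)
    }, 1)
    mean(errs)
  }
  b <- c(bias_at(500L), bias_at(2000L), bias_at(8000L))
  expect_gt(b[1], b[3])
})
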