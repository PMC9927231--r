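test_that("repeat-count thresholds are sharp", {
  bg <- "GCGTTGCAC"
  expect_equal(nrow(find_ssrs(paste0(bg, strrep("A", 9), "GCGTGC"))), 0L)
  hit <- find_ssrs(paste0(bg, strrep("A", 10), "GCGTGC"))
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$motif, "A")
  expect_equal(hit$n_repeats, 10L)
  expect_equal(hit$end - hit$start + 1L, 10L)
})

test_that("units are reported at their minimal period only", {
  ## a poly-A run must not double-report as unit "AA"; an AT run must not
  ## qualify as the non-primitive tetramer "ATAT"
  r <- find_ssrs(paste0("GCGC", strrep("A", 14), "GCGC", strrep("AT", 8), "GC"))
  expect_equal(nrow(r), 1L)      # the two runs are < 100 bp apart: compound
  expect_identical(r$kind, "compound")
  expect_identical(r$motif, "A+AT")
  far <- find_ssrs(paste0("GCGC", strrep("A", 14), random_seq(150, seed = 3),
                          strrep("AT", 8), "GC"), ssr_config())
  simple <- far[far$kind == "simple", ]
  expect_setequal(simple$motif, c("A", "AT"))
  expect_equal(sort(simple$unit_len), c(1L, 2L))
})

test_that("find_ssrs equals the brute-force enumerator on random strings", {
  cfg <- ssr_config(min_repeats = c(6L, 4L, 3L, 3L, 3L, 3L),
                    compound_max_gap = 30L)
  for (seed in 1:6) {
    ## AT-rich background so that repeats actually occur
    s <- random_seq(2000, seed = 600 + seed, gc = 0.25)
    got <- find_ssrs(s, cfg)
    want <- brute_force_ssrs(s, cfg$min_repeats, cfg$compound_max_gap)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = sprintf("seed %d", seed))
    expect_gt(nrow(got), 0L)
  }
})

test_that("SSR sets mirror under reverse complementation", {
  cfg <- ssr_config(min_repeats = c(6L, 4L, 3L, 3L, 3L, 3L))
  s <- random_seq(2000, seed = 71, gc = 0.25)
  n <- nchar(s)
  fwd <- find_ssrs(s, cfg)
  rev <- find_ssrs(revcomp(s), cfg)
  expect_equal(nrow(fwd), nrow(rev))
  ## intervals reflect: [a, b] -> [n - b + 1, n - a + 1]
  expect_equal(sort(n - fwd$end + 1L), sort(rev$start))
  expect_equal(sort(n - fwd$start + 1L), sort(rev$end))
})

test_that("two genomes differing only at SNPs outside repeats share one SSR set", {
  s <- random_seq(4000, seed = 73, gc = 0.25)
  ssrs <- find_ssrs(s)
  in_ssr <- rep(FALSE, nchar(s))
  for (i in seq_len(nrow(ssrs))) in_ssr[ssrs$start[i]:ssrs$end[i]] <- TRUE
  ch <- strsplit(s, "")[[1]]
  set.seed(74)
  cand <- which(!in_ssr)
  pos <- sample(cand[cand > 105 & cand < 3895], 12)
  for (p in pos) {
    ## avoid extending a homopolymer through the substituted base
    ch[p] <- setdiff(c("A", "C", "G", "T"), c(ch[p], ch[p - 1L], ch[p + 1L]))[1L]
  }
  s2 <- paste(ch, collapse = "")
  expect_equal(find_ssrs(s2), ssrs)
})

test_that("compound SSRs merge within the gap and count once", {
  s <- paste0("CGTGC", strrep("A", 12), "GCGT", strrep("TA", 7), "CGGC")
  r <- find_ssrs(s)
  expect_equal(nrow(r), 1L)
  expect_identical(r$kind, "compound")
  expect_equal(r$n_parts, 2L)
  s_far <- paste0("CGTGC", strrep("A", 12), random_seq(150, seed = 75),
                  strrep("TA", 7), "CGGC")
  r2 <- find_ssrs(s_far)
  expect_equal(sum(r2$kind == "simple"), 2L)
})

test_that("location classification conserves the SSR total", {
  pair <- make_cytotype_pair(small_cfg(seed = 7))
  ssrs <- find_ssrs(pair$type1, ssr_config(min_repeats = c(8L, 5L, 4L, 4L, 4L, 4L)))
  res <- classify_ssr_locations(ssrs, pair$type1)
  expect_equal(sum(res$counts), nrow(ssrs))
  expect_named(res$counts, c("CDS", "intron", "intergenic"))
  smry <- summarize_ssrs(ssrs)
  expect_equal(smry$total, nrow(ssrs))
  expect_equal(smry$n_compound + sum(smry$by_unit_len), smry$total)
})
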