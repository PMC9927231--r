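test_that("pairwise diversity counts mismatches over comparable sites", {
  expect_equal(pairwise_pi("ACGT", "ACGT"), 0)
  expect_equal(pairwise_pi("AAAA", "AAAT"), 0.25)
  ## gaps and N excluded from both numerator and denominator
  expect_equal(pairwise_pi("AC-TN", "ACGTA"), 0)
  expect_equal(pairwise_pi("ACGTT", "ACNTA"), 0.25)
  expect_error(pairwise_pi("NNN", "AAA"), "comparable")
  expect_error(pairwise_pi("AA", "AAA"), "equal length")
  for (seed in 1:5) {
    a <- random_seq(300, seed = 800 + seed)
    b <- random_seq(300, seed = 900 + seed)
    expect_equal(pairwise_pi(a, b), oracle_pi(a, b))
  }
})

test_that("sliding windows match hand-computed pair averages", {
  seqs <- c(s1 = "AAAAAAAAAAAAAAAAAAAA",
            s2 = "AAAAAAAAAATTAAAAAAAA",
            s3 = "CAAAAAAAAAAAAAAAAAAT",
            s4 = "AAAAA-AAAAAAAAAAAAAA")
  m <- alignment_matrix(seqs)
  prof <- sliding_window_pi(m, window = 10, step = 5)
  expect_length(prof$pi, 3L)       # floor((20 - 10) / 5) + 1
  pairs <- combn(4, 2)
  by_hand <- function(from, to) {
    mean(apply(pairs, 2, function(ij)
      oracle_pi(substr(seqs[ij[1]], from, to), substr(seqs[ij[2]], from, to))))
  }
  expect_equal(prof$pi, c(by_hand(1, 10), by_hand(6, 15), by_hand(11, 20)))
  expect_equal(prof$mean_pi, mean(apply(pairs, 2, function(ij)
    oracle_pi(seqs[ij[1]], seqs[ij[2]]))))
})

test_that("all-identical alignments have zero diversity everywhere", {
  seqs <- setNames(rep(random_seq(5000, seed = 81), 5), paste0("s", 1:5))
  prof <- sliding_window_pi(alignment_matrix(seqs))
  expect_true(all(prof$pi == 0))
  expect_equal(prof$mean_pi, 0)
  expect_length(prof$pi, (5000 - 1200) %/% 400 + 1)
  expect_error(sliding_window_pi(alignment_matrix(seqs), window = 6000),
               "longer than")
  expect_error(sliding_window_pi(alignment_matrix(seqs[1])), "at least 2")
})

test_that("mean diversity equals the per-site average on gap-free data", {
  set.seed(82)
  base <- random_seq(400)
  seqs <- vapply(1:6, function(i) {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(400, 10)
    for (p in pos) ch[p] <- sample(c("A", "C", "G", "T"), 1)
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:6)
  prof <- sliding_window_pi(alignment_matrix(seqs), window = 400, step = 400)
  expect_equal(prof$mean_pi, oracle_site_pi_mean(seqs), tolerance = 1e-12)
})

test_that("diversity is invariant under sample reordering", {
  pair <- make_cytotype_pair(small_cfg(seed = 7))
  pop <- simulate_population(pair)
  m <- pop$alignment
  perm <- rev(seq_along(m$ids))
  m2 <- alignment_matrix(setNames(m$seqs[perm], m$ids[perm]),
                         excluded = m$excluded)
  p1 <- sliding_window_pi(m, window = 2000, step = 1000)
  p2 <- sliding_window_pi(m2, window = 2000, step = 1000)
  expect_equal(p1$pi, p2$pi)
  expect_equal(p1$mean_pi, p2$mean_pi)
})

test_that("haplotype tabulation collapses identical allele vectors", {
  expect_equal(build_haplotype_table(list(a = variant_table(),
                                          b = variant_table()))$n_haplotypes, 1L)
  nested <- list(
    a = data.frame(pos = 10L, ref = "A", alt = "G", type = "SNP"),
    b = data.frame(pos = c(10L, 20L), ref = c("A", "C"), alt = c("G", "T"),
                   type = "SNP"),
    c = data.frame(pos = c(10L, 20L, 30L), ref = c("A", "C", ""),
                   alt = c("G", "T", "AA"), type = c("SNP", "SNP", "INS")))
  ht <- build_haplotype_table(nested)
  expect_equal(ht$n_haplotypes, 3L)
  expect_equal(nrow(ht$loci), 3L)
  conflicting <- list(a = data.frame(pos = c(10L, 10L), ref = "A",
                                     alt = c("G", "T"), type = "SNP"))
  expect_error(build_haplotype_table(conflicting), "conflicting")
  ## exclusivity flags with group labels
  groups <- c(a = "g1", b = "g1", c = "g2")
  ht2 <- build_haplotype_table(nested, groups = groups)
  expect_identical(ht2$loci$exclusive, c(FALSE, FALSE, TRUE))
})

test_that("Jukes-Cantor distances follow the closed form and its domain", {
  ident <- alignment_matrix(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(unname(jc_distance_matrix(ident)["a", "b"]), 0)
  ## small-p limit: d ~ p
  p <- 3e-4
  expect_equal(-0.75 * log(1 - 4 / 3 * p), p, tolerance = 1e-3)
  set.seed(83)
  base_seq <- random_seq(600)
  mutate <- function(s, n_mut) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), n_mut))
      ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
    paste(ch, collapse = "")
  }
  seqs <- c(x = base_seq, y = mutate(base_seq, 30), z = mutate(base_seq, 60))
  m <- alignment_matrix(seqs)
  d <- jc_distance_matrix(m)
  for (ij in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    pd <- pairwise_pi(seqs[ij[1]], seqs[ij[2]])
    expect_equal(d[ij[1], ij[2]], -0.75 * log(1 - 4 / 3 * pd))
  }
  ## independent implementation: ape's JC69 on the same alignment
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  expect_equal(unname(as.matrix(ape::dist.dna(bin, model = "JC69"))),
               unname(d), tolerance = 1e-10)
  far <- alignment_matrix(c(a = strrep("A", 100), b = strrep("C", 100)))
  expect_error(jc_distance_matrix(far), "0.75")
})

test_that("neighbor joining recovers additive trees exactly", {
  ## additive distances from a known 4-taxon tree:
  ## ((A:1,B:2):1.5,(C:3,D:4):0.5)
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 6
  d["A", "D"] <- d["D", "A"] <- 7
  d["B", "C"] <- d["C", "B"] <- 7
  d["B", "D"] <- d["D", "B"] <- 8
  d["C", "D"] <- d["D", "C"] <- 7
  nwk <- nj_tree(d)
  tr <- ape::read.tree(text = nwk)
  truth <- ape::read.tree(text = "((A:1,B:2):1.5,(C:3,D:4):0.5);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth))[1], 0)
  ## additivity: path distances reproduce the input matrix
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(d), rownames(d)]),
               unname(d), tolerance = 1e-10)
  expect_true(has_bipartition(nwk, c("A", "B")))
  expect_false(has_bipartition(nwk, c("A", "C")))
  bad <- d; bad["A", "B"] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("three taxa yield the unique additive unrooted topology", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- ape::read.tree(text = nj_tree(d))
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_equal(unname(ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]),
               unname(d), tolerance = 1e-10)
})
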