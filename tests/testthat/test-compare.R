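test_that("identical sequences chain into one forward block and no variants", {
  s <- random_seq(10000, seed = 21)
  chain <- anchor_align(s, s)
  expect_equal(nrow(chain$blocks), 1L)
  expect_identical(chain$blocks$orientation, "forward")
  expect_equal(chain$blocks$ref_start, 1L)
  expect_equal(chain$blocks$ref_end, 10000L)
  expect_equal(nrow(call_variants(s, s, chain = chain)), 0L)
  expect_equal(nrow(detect_inversions(chain)), 0L)
})

test_that("a sequence against its reverse complement is one inverted block", {
  s <- random_seq(8000, seed = 22)
  chain <- anchor_align(s, revcomp(s))
  expect_equal(nrow(chain$blocks), 1L)
  expect_identical(chain$blocks$orientation, "inverted")
  expect_equal(chain$blocks$ref_start, 1L)
  expect_equal(chain$blocks$ref_end, 8000L)
})

test_that("hand-implanted SNPs and a deletion are recovered exactly", {
  ref <- random_seq(5000, seed = 23)
  snp_pos <- c(500L, 1500L, 2500L, 3500L, 4200L)
  ch <- strsplit(ref, "")[[1]]
  alt <- vapply(snp_pos, function(p)
    setdiff(c("A", "C", "G", "T"), ch[p])[1L], "")
  truth <- variant_table(
    pos = c(snp_pos, 3000L),
    ref = c(ch[snp_pos], paste(ch[3000:3009], collapse = "")),
    alt = c(alt, ""),
    type = c(rep("SNP", 5), "DEL"))
  ## reject the fixed positions if the deletion context is left-shiftable
  expect_false(ch[2999] == ch[3009])
  query <- apply_variants(ref, truth)
  called <- call_variants(ref, query)
  expect_equal(variant_key(called), variant_key(truth))
})

test_that("implant-recover is exact on simulated cytotype pairs", {
  for (seed in c(7, 19)) {
    pair <- make_cytotype_pair(small_cfg(seed = seed))
    chain <- anchor_align(pair$type1, pair$type2)
    called <- call_variants(pair$type1, pair$type2, chain = chain)
    expect_equal(variant_key(called), variant_key(pair$truth$variants))
    inv <- detect_inversions(chain)
    expect_equal(nrow(inv), 1L)
    expect_equal(c(inv$ref_start, inv$ref_end), pair$truth$inversion)
    expect_equal(inv$length, 230L)
  }
})

test_that("applying called variants to the reference reconstructs the query", {
  pair <- make_cytotype_pair(small_cfg(seed = 31, inversion_len = 0L))
  called <- call_variants(pair$type1, pair$type2)
  expect_identical(apply_variants(pair$type1$sequence, called),
                   pair$type2$sequence)
})

test_that("inversion calls are symmetric in ref and query", {
  pair <- make_cytotype_pair(small_cfg(seed = 7))
  inv_ab <- detect_inversions(anchor_align(pair$type1, pair$type2))
  inv_ba <- detect_inversions(anchor_align(pair$type2, pair$type1))
  expect_equal(inv_ab$length, inv_ba$length)
  expect_equal(c(inv_ab$ref_start, inv_ab$ref_end),
               c(inv_ba$q_start, inv_ba$q_end))
  expect_equal(c(inv_ab$q_start, inv_ab$q_end),
               c(inv_ba$ref_start, inv_ba$ref_end))
})

test_that("adjacent substitutions are separate SNPs unless MNP merging is on", {
  ref <- random_seq(3000, seed = 41)
  ch <- strsplit(ref, "")[[1]]
  pos <- 1500:1502
  alt <- vapply(pos, function(p) setdiff(c("A", "C", "G", "T"), ch[p])[1L], "")
  truth <- variant_table(pos = pos, ref = ch[pos], alt = alt,
                         type = rep("SNP", 3))
  query <- apply_variants(ref, truth)
  called <- call_variants(ref, query)
  expect_equal(nrow(called), 3L)
  expect_true(all(called$type == "SNP"))
  merged <- call_variants(ref, query, merge_mnp = TRUE)
  expect_equal(nrow(merged), 1L)
  expect_identical(merged$type, "MNP")
  expect_equal(nchar(merged$ref), 3L)
})

test_that("genomic context classification follows annotation", {
  feats <- list(gene_feature("gA", "CDS", "+", rbind(c(101, 160), c(221, 280))),
                gene_feature("tX", "tRNA", "+", rbind(c(400, 470))))
  p <- plastome("toy", random_seq(600, seed = 43), features = feats)
  ctx <- classify_region(c(130L, 190L, 240L, 350L, 430L), p)
  expect_identical(ctx$region,
                   c("CDS", "intron", "CDS", "intergenic", "intergenic"))
  expect_identical(ctx$gene[1:3], c("gA", "gA", "gA"))
  expect_true(is.na(ctx$gene[4]))
})

test_that("coding effects match a full-translation oracle on both strands", {
  for (strand in c("+", "-")) {
    set.seed(if (strand == "+") 51 else 52)
    n <- 400L
    seqv <- strsplit(random_seq(n), "")[[1]]
    exons <- rbind(c(101L, 160L), c(201L, 260L))
    if (strand == "-") exons <- exons[2:1, , drop = FALSE]
    f <- gene_feature("gO", "CDS", strand, exons)
    p <- plastome("toy", paste(seqv, collapse = ""), features = list(f))
    for (pos in c(101:130, 145:160, 201:215, 246:260)) {
      for (alt in setdiff(c("A", "C", "G", "T"), seqv[pos])) {
        expect_identical(annotate_effect(pos, seqv[pos], alt, p),
                         oracle_effect(pos, alt, p),
                         label = sprintf("strand %s pos %d alt %s", strand, pos, alt))
      }
    }
  }
})

test_that("alternative GTG/ACG initiation translates as Met at codon 1", {
  seqv <- strsplit(random_seq(200, seed = 53), "")[[1]]
  seqv[101:112] <- strsplit("GTGAAACCCTAA", "")[[1]]
  p_alt <- plastome("toy", paste(seqv, collapse = ""),
                    features = list(gene_feature("rps19x", "CDS", "+",
                                                 rbind(c(101, 112)),
                                                 alt_start_ok = TRUE)))
  ## GTG->ATG with alt starts allowed: both are initiation Met, synonymous
  expect_identical(annotate_effect(101, "G", "A", p_alt), "synonymous")
  p_std <- plastome("toy", paste(seqv, collapse = ""),
                    features = list(gene_feature("gS", "CDS", "+",
                                                 rbind(c(101, 112)))))
  ## without the flag GTG is plain Val, so the change is V1M
  expect_identical(annotate_effect(101, "G", "A", p_std), "V1M")
})

test_that("a CDS with broken frame errors unless flagged pseudo", {
  seqv <- random_seq(200, seed = 54)
  p_bad <- plastome("toy", seqv,
                    features = list(gene_feature("gB", "CDS", "+",
                                                 rbind(c(101, 110)))))
  expect_error(annotate_effect(105, substr(seqv, 105, 105), "A", p_bad),
               "divisible by 3")
  p_ok <- plastome("toy", seqv,
                   features = list(gene_feature("gB", "CDS", "+",
                                                rbind(c(101, 110)),
                                                is_pseudo = TRUE)))
  expect_silent(annotate_effect(105, substr(seqv, 105, 105), "A", p_ok))
})

test_that("diagnostic loci are the SNP subset keyed by position", {
  s <- random_seq(6000, seed = 55)
  expect_equal(nrow(diagnostic_loci(s, s)), 0L)
  pair <- make_cytotype_pair(small_cfg(seed = 7))
  dl <- diagnostic_loci(pair$type1, pair$type2)
  expect_equal(dl$pos, pair$truth$loci$pos)
  expect_identical(dl$allele_a, pair$truth$loci$allele_a)
  expect_identical(dl$allele_b, pair$truth$loci$allele_b)
  expect_true(all(diff(dl$pos) > 0))
  expect_true(all(dl$allele_a != dl$allele_b))
})
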