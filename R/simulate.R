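## Synthetic-data generator.
##
## Emulates the statistical structure of a two-cytotype plastome study:
## a random circular genome with an exact IR pair and sparse gene
## annotation; a second cytotype derived from it by implanting diagnostic
## SNPs, indels and one short inversion; a 43-sample population in which
## the first cytotype splits into geographic subgroups; and per-site
## base-count profiles of mixed-cytotype individuals with sequencing
## error, strand splitting, quality failures and an optional
## organellar-insert background. Every generator returns its truth set so
## analysis modules can be tested by implant-and-recover, and all outputs
## are bit-identical for identical seeds and configs.

#' Simulation configuration
#'
#' Defaults mirror the study conditions of a deep-sequenced two-cytotype
#' plastome survey: a 161,537 bp genome with 30,896 bp IRs and a
#' 13,632 bp SSC, 105 diagnostic SNPs plus 36 diagnostic indels and one
#' 230 bp inversion between the cytotypes, 25 intra-type subgroup
#' variants, ~8,175x plastid depth, 0.2% per-base error and ~45x nuclear
#' depth, at 36% GC.
#'
#' @param seed Integer seed; every generator call is reproducible from it.
#' @param genome_len,ir_len,ssc_len Genome architecture (bp); the LSC
#'   length is implied.
#' @param n_diag_snps,n_diag_indels Number of diagnostic SNPs/indels
#'   separating the two cytotypes.
#' @param inversion_len Length (bp) of the implanted cytotype inversion
#'   (0 for none).
#' @param n_subgroup_variants Intra-type variants available to population
#'   subgroups.
#' @param mixture_fraction Minor-cytotype fraction in `[0, 0.5]` for
#'   base-count simulation.
#' @param depth Total per-site read depth at diagnostic loci.
#' @param error_rate Per-base sequencing error rate.
#' @param nuclear_depth Mean nuclear coverage (the NUMT-guard comparator).
#' @param gc GC content of the random genome.
#' @param qual_fail_rate Fraction of reads drawn below the Phred filter.
#' @param min_spacing Minimum distance (bp) between implanted events.
#' @param n_cds_lsc,n_trna_lsc,n_cds_ssc,n_rrna_ir Annotation density.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, genome_len = 161537L, ir_len = 30896L,
                              ssc_len = 13632L, n_diag_snps = 105L,
                              n_diag_indels = 36L, inversion_len = 230L,
                              n_subgroup_variants = 25L,
                              mixture_fraction = 0, depth = 8175L,
                              error_rate = 0.002, nuclear_depth = 45,
                              gc = 0.36, qual_fail_rate = 0.05,
                              min_spacing = 40L, n_cds_lsc = 18L,
                              n_trna_lsc = 6L, n_cds_ssc = 3L,
                              n_rrna_ir = 2L) {
  lsc_len <- genome_len - ssc_len - 2L * ir_len
  if (lsc_len <= 0L) stop("inconsistent lengths: implied LSC is not positive")
  stopifnot(mixture_fraction >= 0, mixture_fraction <= 0.5,
            n_diag_snps >= 0L, n_diag_indels >= 0L, inversion_len >= 0L,
            depth >= 0L, error_rate >= 0, error_rate < 1)
  structure(as.list(environment()), class = "simulation_config")
}

random_dna <- function(n, gc = 0.36) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## place non-overlapping gene features across a region by slotting
place_genes_in_region <- function(region, n_cds, n_trna, prefix) {
  feats <- list()
  total <- n_cds + n_trna
  if (total == 0L) return(feats)
  a <- region[1L]; b <- region[2L]
  w <- (b - a + 1L) %/% total
  kinds <- sample(c(rep("CDS", n_cds), rep("tRNA", n_trna)))
  for (i in seq_len(total)) {
    slot_a <- a + (i - 1L) * w
    if (kinds[i] == "CDS") {
      cds_len <- 3L * sample(100:400, 1L)
      two_exon <- runif(1) < 0.4
      intron_len <- if (two_exon) sample(150:500, 1L) else 0L
      span <- cds_len + intron_len
      if (span + 40L > w) { cds_len <- 3L * 80L; intron_len <- 0L; span <- cds_len }
      if (span + 40L > w) next
      start <- slot_a + sample.int(w - span - 20L, 1L)
      strand <- sample(c("+", "-"), 1L)
      if (intron_len > 0L) {
        e1 <- 3L * sample.int(cds_len %/% 3L - 1L, 1L)
        ex <- rbind(c(start, start + e1 - 1L),
                    c(start + e1 + intron_len, start + span - 1L))
        if (strand == "-") ex <- ex[2:1, , drop = FALSE]
      } else ex <- rbind(c(start, start + cds_len - 1L))
      feats[[length(feats) + 1L]] <- gene_feature(
        sprintf("%sg%02d", prefix, i), "CDS", strand, ex)
    } else {
      len <- sample(70:90, 1L)
      if (len + 40L > w) next
      start <- slot_a + sample.int(w - len - 20L, 1L)
      feats[[length(feats) + 1L]] <- gene_feature(
        sprintf("%strn%02d", prefix, i), "tRNA", sample(c("+", "-"), 1L),
        rbind(c(start, start + len - 1L)))
    }
  }
  feats
}

## masks of positions eligible for variant implantation
eligibility_masks <- function(p, cfg, inversion = NULL) {
  n <- nchar(p$sequence)
  lsc_len <- cfg$genome_len - cfg$ssc_len - 2L * cfg$ir_len
  single_copy <- rep(FALSE, n)
  single_copy[1:lsc_len] <- TRUE
  single_copy[(lsc_len + cfg$ir_len + 1L):(lsc_len + cfg$ir_len + cfg$ssc_len)] <- TRUE
  exon <- rep(FALSE, n)
  cds_exon <- rep(FALSE, n)
  for (f in p$features) {
    for (e in seq_len(nrow(f$exons))) {
      exon[f$exons[e, 1L]:f$exons[e, 2L]] <- TRUE
      if (f$kind == "CDS") cds_exon[f$exons[e, 1L]:f$exons[e, 2L]] <- TRUE
    }
  }
  ok <- single_copy
  buf <- 60L
  ok[seq_len(min(buf, n))] <- FALSE
  ok[seq.int(max(1L, n - buf), n)] <- FALSE
  ## keep events clear of the IR junctions
  for (bnd in cumsum(c(lsc_len, cfg$ir_len, cfg$ssc_len)))
    ok[max(1L, bnd - buf):min(n, bnd + buf)] <- FALSE
  if (!is.null(inversion))
    ok[max(1L, inversion[1L] - buf):min(n, inversion[2L] + buf)] <- FALSE
  list(ok_snp = ok, ok_indel = ok & !exon, cds_exon = cds_exon, exon = exon)
}

## implant variants at mutually spaced positions; returns a variant_table
## whose records are already left-normalized (placement enforces it)
place_variants <- function(seq_chars, masks, n_snps, n_indels,
                           min_spacing, avoid = integer()) {
  taken <- avoid
  pick_pos <- function(ok_mask, halo) {
    for (try in 1:20000) {
      pos <- sample(which(ok_mask), 1L)
      if (length(taken) == 0L || min(abs(taken - pos)) > min_spacing) {
        if (halo(pos)) return(pos)
      }
    }
    stop("could not place variant after bounded retries; loosen spacing or counts")
  }
  recs <- list()
  for (i in seq_len(n_snps)) {
    pos <- pick_pos(masks$ok_snp, function(p) TRUE)
    taken <- c(taken, pos)
    refb <- seq_chars[pos]
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    recs[[length(recs) + 1L]] <- list(pos = pos, ref = refb, alt = altb, type = "SNP")
  }
  n_ins <- n_indels %/% 2L + n_indels %% 2L
  for (i in seq_len(n_indels)) {
    is_ins <- i <= n_ins
    len <- sample(1:10, 1L)
    if (is_ins) {
      ## pos = left flank; stability: inserted run must not left-shift
      pos <- pick_pos(masks$ok_indel, function(p) masks$ok_indel[min(p + 1L, length(seq_chars))])
      ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      while (ins[len] == seq_chars[pos])
        ins[len] <- sample(c("A", "C", "G", "T"), 1L)
      taken <- c(taken, pos)
      recs[[length(recs) + 1L]] <- list(pos = pos, ref = "",
                                        alt = paste(ins, collapse = ""), type = "INS")
    } else {
      pos <- pick_pos(masks$ok_indel, function(p)
        p + len - 1L <= length(seq_chars) &&
          all(masks$ok_indel[p:(p + len - 1L)]) &&
          seq_chars[p - 1L] != seq_chars[p + len - 1L])
      taken <- c(taken, pos, pos + len - 1L)
      recs[[length(recs) + 1L]] <- list(
        pos = pos, ref = paste(seq_chars[pos:(pos + len - 1L)], collapse = ""),
        alt = "", type = "DEL")
    }
  }
  if (length(recs) == 0L) return(variant_table())
  df <- data.frame(pos = vapply(recs, function(r) as.integer(r$pos), 1L),
                   ref = vapply(recs, `[[`, "", "ref"),
                   alt = vapply(recs, `[[`, "", "alt"),
                   type = vapply(recs, `[[`, "", "type"))
  df <- df[order(df$pos), ]
  variant_table(df$pos, df$ref, df$alt, df$type)
}

#' Reverse-complement a segment of a sequence in place
#'
#' @param seq DNA string.
#' @param start,end 1-based inclusive interval to invert.
#' @return The edited sequence.
#' @export
apply_inversion <- function(seq, start, end) {
  paste0(substr(seq, 1L, start - 1L), revcomp(substr(seq, start, end)),
         substr(seq, end + 1L, nchar(seq)))
}

## shift feature coordinates from cytotype-A to cytotype-B space given the
## indels separating them
shift_features <- function(features, variants) {
  ind <- variants[variants$type %in% c("INS", "DEL"), , drop = FALSE]
  if (nrow(ind) == 0L) return(features)
  shift_of <- function(x) {
    off <- 0L
    for (i in seq_len(nrow(ind))) {
      if (ind$type[i] == "INS" && ind$pos[i] < x) off <- off + nchar(ind$alt[i])
      if (ind$type[i] == "DEL" && ind$pos[i] + nchar(ind$ref[i]) - 1L < x)
        off <- off - nchar(ind$ref[i])
    }
    off
  }
  lapply(features, function(f) {
    f$exons <- f$exons + apply(f$exons, c(1, 2), shift_of)
    f
  })
}

#' Generate a synthetic cytotype pair
#'
#' Builds a random annotated plastome with an exact IR pair, then derives
#' the second cytotype by implanting `n_diag_snps` SNPs, `n_diag_indels`
#' indels (1-10 bp, outside exons) and one inversion of `inversion_len` bp
#' in the LSC, all in single-copy regions at pairwise spacing of at least
#' `min_spacing` bp and clear of the inversion. Implanted indels are
#' placed so their left-normalized representation is the implanted one.
#'
#' @param cfg A [simulation_config()].
#' @return List with `type1` and `type2` ([plastome()]s) and `truth`
#'   (list: `variants` on type1 coordinates, `inversion` interval or
#'   `NULL`, `loci` = the diagnostic SNP subset).
#' @export
make_cytotype_pair <- function(cfg = simulation_config()) {
  with_seed(cfg$seed, {
    lsc_len <- cfg$genome_len - cfg$ssc_len - 2L * cfg$ir_len
    lsc <- random_dna(lsc_len, cfg$gc)
    ira <- random_dna(cfg$ir_len, cfg$gc)
    ssc <- random_dna(cfg$ssc_len, cfg$gc)
    ## keep the IR boundaries non-extendable so the implanted IR pair is
    ## the exact maximal reverse-complement repeat: the bases flanking
    ## the arms (LSC ends, circularly, and SSC ends) must not complement
    while (substr(lsc, lsc_len, lsc_len) == comp_chars(substr(lsc, 1L, 1L)))
      substr(lsc, lsc_len, lsc_len) <- sample(c("A", "C", "G", "T"), 1L)
    while (substr(ssc, 1L, 1L) == comp_chars(substr(ssc, cfg$ssc_len, cfg$ssc_len)))
      substr(ssc, 1L, 1L) <- sample(c("A", "C", "G", "T"), 1L)
    seq_a <- paste0(lsc, ira, ssc, revcomp(ira))

    feats <- c(place_genes_in_region(c(1L, lsc_len), cfg$n_cds_lsc,
                                     cfg$n_trna_lsc, "l"),
               place_genes_in_region(c(lsc_len + cfg$ir_len + 1L,
                                       lsc_len + cfg$ir_len + cfg$ssc_len),
                                     cfg$n_cds_ssc, 0L, "s"))
    ## mirrored rRNA pair inside the IRs
    if (cfg$n_rrna_ir > 0L && cfg$ir_len > 4000L) {
      for (i in seq_len(cfg$n_rrna_ir)) {
        len <- sample(1200:1800, 1L)
        o <- sample.int(cfg$ir_len - len - 200L, 1L)
        sa <- lsc_len + o
        feats[[length(feats) + 1L]] <- gene_feature(
          sprintf("rrn%02d", i), "rRNA", "+", rbind(c(sa, sa + len - 1L)))
        ea <- cfg$genome_len - lsc_len - o + 1L   # mirror position in IRb
        feats[[length(feats) + 1L]] <- gene_feature(
          sprintf("rrn%02db", i), "rRNA", "-", rbind(c(ea - len + 1L, ea)))
      }
    }
    type1 <- plastome("SIM_T1", seq_a, circular = TRUE, features = feats)

    inversion <- NULL
    if (cfg$inversion_len > 0L) {
      masks0 <- eligibility_masks(type1, cfg)
      ok_inv <- masks0$ok_indel
      ok_inv[-seq_len(lsc_len)] <- FALSE   # the short inversion sits in the LSC
      for (try in 1:10000) {
        s <- sample(which(ok_inv), 1L)
        e <- s + cfg$inversion_len - 1L
        if (e > length(ok_inv) || !all(ok_inv[s:e])) next
        ## reject boundary-ambiguous placements: if the flanking bases are
        ## complementary, inverting [s-1, e+1] gives the same sequence and
        ## the implanted interval would not be uniquely recoverable
        if (substr(seq_a, s - 1L, s - 1L) ==
            comp_chars(substr(seq_a, e + 1L, e + 1L))) next
        inversion <- c(s, e)
        break
      }
      if (is.null(inversion)) stop("could not place the inversion")
    }
    seq_chars <- strsplit(seq_a, "", fixed = TRUE)[[1]]
    masks <- eligibility_masks(type1, cfg, inversion)
    variants <- place_variants(seq_chars, masks, cfg$n_diag_snps,
                               cfg$n_diag_indels, cfg$min_spacing)
    seq_b <- if (!is.null(inversion))
      apply_inversion(seq_a, inversion[1L], inversion[2L]) else seq_a
    seq_b <- apply_variants(seq_b, variants)
    type2 <- plastome("SIM_T2", seq_b, circular = TRUE,
                      features = shift_features(feats, variants))
    loci <- variants[variants$type == "SNP", , drop = FALSE]
    loci <- data.frame(pos = loci$pos, allele_a = loci$ref, allele_b = loci$alt,
                       stringsAsFactors = FALSE)
    class(loci) <- c("diagnostic_locus_set", "data.frame")
    list(type1 = type1, type2 = type2, cfg = cfg,
         truth = list(variants = variants, inversion = inversion, loci = loci))
  })
}

#' Default population specification
#'
#' Fifteen programmed haplotypes over 43 samples: one haplotype of 7
#' identical second-cytotype individuals, and 36 first-cytotype
#' individuals split into 14 subgroups (one identical to the reference;
#' one 18-sample clade carrying three shared SNPs with nested subgroups;
#' several singletons), drawing on a pool of 17 subgroup SNPs and 8
#' subgroup indels. Variant indices 1-17 refer to SNPs, 18-25 to indels
#' of the subgroup pool.
#'
#' @return List of class `population_spec` with `haplotypes` (a list of
#'   `list(n, cytotype, variants)`), `n_subgroup_snps`, `n_subgroup_indels`.
#' @export
default_population_spec <- function() {
  H <- list(
    list(n = 7L, cytotype = "Type 2", variants = integer()),
    list(n = 6L, cytotype = "Type 1", variants = c(1L, 2L, 3L, 4L, 5L)),
    list(n = 3L, cytotype = "Type 1", variants = c(1L, 2L, 3L, 4L, 5L, 18L)),
    list(n = 4L, cytotype = "Type 1", variants = c(1L, 2L, 3L, 6L, 7L)),
    list(n = 3L, cytotype = "Type 1", variants = c(1L, 2L, 3L, 8L)),
    list(n = 1L, cytotype = "Type 1", variants = c(1L, 2L, 3L, 9L)),
    list(n = 1L, cytotype = "Type 1", variants = c(1L, 2L, 3L, 19L)),
    list(n = 6L, cytotype = "Type 1", variants = integer()),
    list(n = 2L, cytotype = "Type 1", variants = c(24L, 25L)),
    list(n = 4L, cytotype = "Type 1", variants = c(10L, 11L, 12L)),
    list(n = 2L, cytotype = "Type 1", variants = c(10L, 11L, 13L)),
    list(n = 1L, cytotype = "Type 1", variants = c(14L, 20L)),
    list(n = 1L, cytotype = "Type 1", variants = c(15L, 21L)),
    list(n = 1L, cytotype = "Type 1", variants = c(16L, 22L)),
    list(n = 1L, cytotype = "Type 1", variants = c(17L, 23L)))
  structure(list(haplotypes = H, n_subgroup_snps = 17L, n_subgroup_indels = 8L),
            class = "population_spec")
}

#' Simulate a two-cytotype population of plastomes
#'
#' Realizes the haplotype assignments of a [default_population_spec()]-style
#' specification on a [make_cytotype_pair()] base pair: second-cytotype
#' samples carry all inter-type variants and the inversion; first-cytotype
#' samples carry their subgroup's private variants. The output alignment
#' is exact (built from the truth, no aligner involved), with deletions as
#' gaps, insertions as gap-padded columns, and the inversion region listed
#' as an excluded interval.
#'
#' @param pair A [make_cytotype_pair()] result.
#' @param spec A population specification.
#' @return List with `samples` (data frame: `sample_id`, `cytotype`,
#'   `haplotype`), `alignment` (an [alignment_matrix()]; excluded interval
#'   covers the inversion), `truth` (per-sample variant tables on type1
#'   coordinates in `variant_sets`, plus `subgroup_variants`), and
#'   `expected_pi` (closed-form genome-wide mean diversity implied by the
#'   programmed allele counts).
#' @export
simulate_population <- function(pair, spec = default_population_spec()) {
  cfg <- pair$cfg
  if (length(spec$haplotypes) == 0L) stop("empty sample list")
  with_seed(cfg$seed + 1L, {
    ref <- pair$type1$sequence
    seq_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
    masks <- eligibility_masks(pair$type1, cfg, pair$truth$inversion)
    sub_vars <- place_variants(seq_chars, masks, spec$n_subgroup_snps,
                               spec$n_subgroup_indels, cfg$min_spacing,
                               avoid = pair$truth$variants$pos)
    ## reorder so indices 1..n_snps are SNPs, the rest indels
    sub_vars <- rbind(sub_vars[sub_vars$type == "SNP", ],
                      sub_vars[sub_vars$type != "SNP", ])

    samples <- do.call(rbind, lapply(seq_along(spec$haplotypes), function(h) {
      hs <- spec$haplotypes[[h]]
      data.frame(sample_id = sprintf("S%02d_%02d", h, seq_len(hs$n)),
                 cytotype = hs$cytotype, haplotype = sprintf("H%02d", h))
    }))
    hap_of <- setNames(samples$haplotype, samples$sample_id)

    variant_sets <- list()
    rows <- list()
    ## global insertion column layout: all INS loci any sample may carry
    all_ins <- rbind(
      pair$truth$variants[pair$truth$variants$type == "INS", c("pos", "alt")],
      sub_vars[sub_vars$type == "INS", c("pos", "alt")])
    all_ins <- all_ins[order(all_ins$pos), , drop = FALSE]

    for (h in seq_along(spec$haplotypes)) {
      hs <- spec$haplotypes[[h]]
      own <- sub_vars[hs$variants[hs$variants <= nrow(sub_vars)], , drop = FALSE]
      vset <- if (hs$cytotype == "Type 2")
        rbind(as.data.frame(pair$truth$variants), as.data.frame(own))
      else as.data.frame(own)
      vset <- vset[order(vset$pos), , drop = FALSE]
      ## aligned row: SNP substitutions, deletions as gaps, inversion for
      ## the second cytotype, then insertion columns woven in
      row <- ref
      for (i in seq_len(nrow(vset))) {
        v <- vset[i, ]
        if (v$type == "SNP") substr(row, v$pos, v$pos) <- v$alt
        else if (v$type == "DEL")
          substr(row, v$pos, v$pos + nchar(v$ref) - 1L) <-
            strrep("-", nchar(v$ref))
      }
      if (hs$cytotype == "Type 2" && !is.null(pair$truth$inversion)) {
        inv <- pair$truth$inversion
        substr(row, inv[1L], inv[2L]) <- revcomp(substr(ref, inv[1L], inv[2L]))
      }
      if (nrow(all_ins)) {
        has_ins <- paste(all_ins$pos, all_ins$alt) %in%
          paste(vset$pos[vset$type == "INS"], vset$alt[vset$type == "INS"])
        pieces <- character(0)
        prev <- 1L
        for (i in seq_len(nrow(all_ins))) {
          pieces <- c(pieces, substr(row, prev, all_ins$pos[i]),
                      if (has_ins[i]) all_ins$alt[i]
                      else strrep("-", nchar(all_ins$alt[i])))
          prev <- all_ins$pos[i] + 1L
        }
        row <- paste(c(pieces, substr(row, prev, nchar(row))), collapse = "")
      }
      idx <- which(samples$haplotype == sprintf("H%02d", h))
      for (s in samples$sample_id[idx]) {
        variant_sets[[s]] <- vset
        rows[[s]] <- row
      }
    }

    ## inversion interval in alignment coordinates (insertions shift it)
    excluded <- NULL
    if (!is.null(pair$truth$inversion)) {
      shift_to_aln <- function(x)
        x + if (nrow(all_ins)) sum(nchar(all_ins$alt)[all_ins$pos < x]) else 0L
      excluded <- c(shift_to_aln(pair$truth$inversion[1L]),
                    shift_to_aln(pair$truth$inversion[2L]))
    }
    aln <- alignment_matrix(unlist(rows), excluded = excluded)

    ## closed-form expected genome-wide mean diversity from the programmed
    ## SNP allele counts (inversion masked; indel sites ignored)
    N <- nrow(samples)
    snp_keys <- c(paste0("d", pair$truth$loci$pos), paste0("s", sub_vars$pos[sub_vars$type == "SNP"]))
    carriers <- c(
      setNames(rep(sum(samples$cytotype == "Type 2"), nrow(pair$truth$loci)),
               paste0("d", pair$truth$loci$pos)),
      vapply(which(sub_vars$type == "SNP"), function(i) {
        sum(vapply(seq_along(spec$haplotypes), function(h)
          if (i %in% spec$haplotypes[[h]]$variants) spec$haplotypes[[h]]$n else 0L,
          1L))
      }, 1L))
    L_eff <- nchar(ref) - if (is.null(pair$truth$inversion)) 0L else
      (pair$truth$inversion[2L] - pair$truth$inversion[1L] + 1L)
    expected_pi <- sum(carriers * (N - carriers)) / choose(N, 2) / L_eff

    list(samples = samples, alignment = aln,
         truth = list(variant_sets = variant_sets, subgroup_variants = sub_vars,
                      haplotype = hap_of),
         expected_pi = expected_pi)
  })
}

#' Simulate a base-count profile of a mixed-cytotype sample
#'
#' At every diagnostic locus, allele counts are drawn from a multinomial
#' over the four bases with probabilities
#' `(1-f)*(1-e)` for the major-type allele, `f*(1-e)` for the minor-type
#' allele and `e/3` leakage to each off-allele, then split binomially
#' between strands. A `qual_fail_rate` fraction of reads is drawn below
#' the Phred threshold and recorded in the profile's `qual_fail` table so
#' that [filter_basecounts()] can remove it. Optionally, an
#' organellar-insert background adds `nuclear_depth` reads of the
#' minor-type allele at the masked loci.
#'
#' @param loci A [diagnostic_loci()] set (e.g. `pair$truth$loci`).
#' @param f True minor-cytotype fraction in `[0, 0.5]`.
#' @param cfg A [simulation_config()] (depth, error rate, nuclear depth,
#'   quality-failure rate).
#' @param seed Seed for this draw (defaults to `cfg$seed`).
#' @param sample_id Sample name.
#' @param major `"a"` or `"b"`: which cytotype is the major one.
#' @param numt_loci Optional vector of locus positions carrying an
#'   organellar-insert homolog.
#' @return A [base_count_profile()] with truth attached as attribute
#'   `truth` (list with `f`, `major`).
#' @export
simulate_basecounts <- function(loci, f, cfg = simulation_config(),
                                seed = cfg$seed, sample_id = "sim",
                                major = c("a", "b"), numt_loci = NULL) {
  major <- match.arg(major)
  stopifnot(f >= 0, f <= 0.5)
  if (cfg$depth <= 0L) stop("depth must be positive")
  with_seed(seed, {
    nl <- nrow(loci)
    bases <- c("A", "C", "G", "T")
    maj_allele <- if (major == "a") loci$allele_a else loci$allele_b
    min_allele <- if (major == "a") loci$allele_b else loci$allele_a
    e <- cfg$error_rate
    zero <- integer(nl)
    d <- data.frame(pos = loci$pos, ref = loci$allele_a,
                    A_f = zero, A_r = zero, C_f = zero, C_r = zero,
                    G_f = zero, G_r = zero, T_f = zero, T_r = zero,
                    ins_f = zero, ins_r = zero, del_f = zero, del_r = zero,
                    depth = zero)
    qf <- d
    for (i in seq_len(nl)) {
      pr <- rep(e / 3, 4L)
      pr[match(maj_allele[i], bases)] <- (1 - f) * (1 - e) + f * e / 3
      pr[match(min_allele[i], bases)] <- f * (1 - e) + (1 - f) * e / 3
      cnt <- as.integer(rmultinom(1L, cfg$depth, pr))
      if (!is.null(numt_loci) && loci$pos[i] %in% numt_loci)
        cnt[match(min_allele[i], bases)] <-
          cnt[match(min_allele[i], bases)] + as.integer(round(cfg$nuclear_depth))
      fwd <- rbinom(4L, cnt, 0.5)
      rev <- cnt - fwd
      fail_f <- rbinom(4L, fwd, cfg$qual_fail_rate)
      fail_r <- rbinom(4L, rev, cfg$qual_fail_rate)
      d[i, paste0(bases, "_f")] <- fwd
      d[i, paste0(bases, "_r")] <- rev
      qf[i, paste0(bases, "_f")] <- fail_f
      qf[i, paste0(bases, "_r")] <- fail_r
    }
    d$depth <- rowSums(d[, BC_DEPTH_COLS])
    qf$depth <- rowSums(qf[, BC_DEPTH_COLS])
    prof <- base_count_profile(sample_id, d, nuclear_depth = cfg$nuclear_depth,
                               qual_fail = qf)
    attr(prof, "truth") <- list(f = f, major = major)
    prof
  })
}
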