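## Independent oracles and small fixture builders. These deliberately use
## different algorithms from the package (naive enumeration, full-protein
## translation diffs, position-by-position counting) so that agreement is
## meaningful.

## scaled-down study conditions for fast module tests
small_cfg <- function(seed = 7, ...) {
  base <- list(seed = seed, genome_len = 24000L, ir_len = 5000L,
               ssc_len = 3000L, n_diag_snps = 15L, n_diag_indels = 6L,
               inversion_len = 230L, n_cds_lsc = 5L, n_trna_lsc = 2L,
               n_cds_ssc = 1L, n_rrna_ir = 1L)
  do.call(simulation_config, utils::modifyList(base, list(...)))
}

random_seq <- function(n, seed = NULL, gc = 0.4) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

variant_key <- function(vt) {
  vt <- as.data.frame(vt)
  sort(paste(vt$pos, vt$ref, vt$alt, vt$type))
}

## --- SSR brute force: O(n^2 * 6) enumeration with explicit while-loops ---

bf_is_primitive <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d) next
    if (paste(rep(substr(unit, 1L, d), u / d), collapse = "") == unit)
      return(FALSE)
  }
  TRUE
}

brute_force_ssrs <- function(seq, min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                             compound_max_gap = 100L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  rows <- list()
  for (u in 1:6) {
    i <- 1L
    while (i + u * min_repeats[u] - 1L <= n) {
      ## left-maximal period-u run starting at i
      if (i > 1L && i + u - 1L < n && ch[i - 1L] == ch[i - 1L + u]) { i <- i + 1L; next }
      e <- i + u - 1L
      while (e + 1L <= n && ch[e + 1L] == ch[e + 1L - u]) e <- e + 1L
      n_rep <- (e - i + 1L) %/% u
      unit <- paste(ch[i:(i + u - 1L)], collapse = "")
      if (n_rep >= min_repeats[u] && bf_is_primitive(unit) &&
          !grepl("N", unit, fixed = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          start = i, end = i + u * n_rep - 1L, motif = unit,
          unit_len = u, n_repeats = n_rep)
      i <- i + 1L
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit_len = integer(), n_repeats = integer(),
                      kind = character(), n_parts = integer()))
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$start, df$end), ]
  ## compound merge, written as an explicit scan
  out <- list()
  cur <- df[1L, ]
  cur_parts <- list(df[1L, ])
  flush <- function(cur, parts) {
    if (length(parts) == 1L) data.frame(cur, kind = "simple", n_parts = 1L)
    else data.frame(start = min(vapply(parts, function(p) p$start, 1)),
                    end = max(vapply(parts, function(p) p$end, 1)),
                    motif = paste(vapply(parts, function(p) p$motif, ""), collapse = "+"),
                    unit_len = NA_integer_, n_repeats = NA_integer_,
                    kind = "compound", n_parts = length(parts))
  }
  if (nrow(df) > 1L) {
    max_end <- df$end[1L]
    for (r in 2:nrow(df)) {
      if (df$start[r] - max_end - 1L <= compound_max_gap) {
        cur_parts[[length(cur_parts) + 1L]] <- df[r, ]
      } else {
        out[[length(out) + 1L]] <- flush(cur, cur_parts)
        cur <- df[r, ]; cur_parts <- list(df[r, ])
      }
      max_end <- max(max_end, df$end[r])
    }
  }
  out[[length(out) + 1L]] <- flush(cur, cur_parts)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start), ]
}

## --- nucleotide diversity by explicit per-position counting ---

oracle_pi <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mism <- 0L; comp <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% c("A", "C", "G", "T") && bv[i] %in% c("A", "C", "G", "T")) {
      comp <- comp + 1L
      if (av[i] != bv[i]) mism <- mism + 1L
    }
  }
  if (comp == 0L) stop("no comparable sites")
  mism / comp
}

## mean per-site diversity over an alignment (gap-free case)
oracle_site_pi_mean <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  ns <- nrow(mat)
  npair <- choose(ns, 2)
  site_pi <- apply(mat, 2L, function(col) {
    tab <- table(col)
    (npair - sum(choose(tab, 2))) / npair
  })
  mean(site_pi)
}

## --- coding-effect oracle: translate whole protein before/after ---

oracle_effect <- function(pos, alt, p, feature_idx = 1L) {
  f <- p$features[[feature_idx]]
  cds_of <- function(seq) {
    parts <- vapply(seq_len(nrow(f$exons)), function(e) {
      s <- substr(seq, f$exons[e, 1L], f$exons[e, 2L])
      if (f$strand == "-") revcomp(s) else s
    }, "")
    substr(paste(parts, collapse = ""), f$codon_start, 1e9)
  }
  translate_full <- function(cds) {
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds), no.init.codon = TRUE)), "")[[1]]
    start <- substr(cds, 1, 3)
    if (start == "ATG" || (f$alt_start_ok && start %in% c("GTG", "ACG")))
      aa[1] <- "M"
    aa
  }
  mut <- p$sequence
  substr(mut, pos, pos) <- alt
  aa_ref <- translate_full(cds_of(p$sequence))
  aa_alt <- translate_full(cds_of(mut))
  d <- which(aa_ref != aa_alt)
  if (length(d) == 0L) "synonymous"
  else sprintf("%s%d%s", aa_ref[d[1L]], d[1L], aa_alt[d[1L]])
}
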