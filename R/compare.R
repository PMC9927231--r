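## Assembly-vs-assembly comparison.
##
## Two plastome assemblies are aligned by chaining k-mers that occur
## exactly once in each genome (counting both strands, which keeps the IR
## copies out of the anchor set and lets chaining pick one consistent
## placement). Runs of collinear anchors become forward or inverted
## blocks; the short unanchored gaps between consecutive anchors inside a
## forward block are realigned with an affine-gap Needleman-Wunsch and the
## differences emitted as left-normalized SNP/INS/DEL records. Inverted
## blocks are reported separately as inversion calls.

#' Anchor-based alignment of two plastome assemblies
#'
#' @param ref,query [plastome()]s or DNA strings.
#' @param k Anchor k-mer length. Anchors are k-mers unique in both genomes
#'   (both strands counted).
#' @param max_gap Maximum reference-side jump (bp) absorbed into one
#'   block. The default is chosen to span a full plastome inverted repeat
#'   (whose interior k-mers are two-copy and yield no anchors).
#' @param indel_tol Maximum difference between the reference-side and
#'   query-side jumps between consecutive anchors of one block.
#' @param min_block_anchors Blocks supported by fewer anchors are dropped
#'   as noise.
#' @return An object of class `anchor_chain`: a list with `blocks` (data
#'   frame with `ref_start`, `ref_end`, `q_start`, `q_end`, `orientation`,
#'   `n_anchors`), `anchors` (per-anchor positions with block ids),
#'   `k`, and the two genome lengths.
#' @export
anchor_align <- function(ref, query, k = 31L, max_gap = 35000L,
                         indel_tol = 1000L, min_block_anchors = 2L) {
  r <- as_sequence(ref)
  q <- as_sequence(query)
  if (nchar(r) < k || nchar(q) < k)
    stop("both sequences must be at least k = ", k, " bp long")
  nq <- nchar(q)

  ref_km <- kmer_starts(r, k)
  ref_rc_km <- kmer_starts(revcomp(r), k)
  q_km <- kmer_starts(q, k)
  q_rc_km <- kmer_starts(revcomp(q), k)

  ## unique-in-genome counting both strands
  ref_tab <- table(c(ref_km, ref_rc_km))
  q_tab <- table(c(q_km, q_rc_km))
  ref_uni <- names(ref_tab)[ref_tab == 1L]
  q_uni <- names(q_tab)[q_tab == 1L]
  shared <- intersect(ref_uni, q_uni)
  if (length(shared) == 0L)
    stop("no k-mers unique in both genomes are shared; try a smaller k")

  rp <- match(shared, ref_km)        # unique, so first match is the match
  qf <- match(shared, q_km)
  qr <- match(shared, q_rc_km)
  keep <- !is.na(rp) & (!is.na(qf) | !is.na(qr))
  rp <- rp[keep]; qf <- qf[keep]; qr <- qr[keep]
  strand <- ifelse(!is.na(qf), "+", "-")
  ## forward-strand query coordinate of the anchor's k-mer start
  qp <- ifelse(!is.na(qf), qf, nq - qr - k + 2L)
  ord <- order(rp)
  rp <- rp[ord]; qp <- qp[ord]; strand <- strand[ord]
  if (length(rp) == 0L)
    stop("no k-mers unique in both genomes are shared; try a smaller k")

  ## chain: break where orientation flips or collinearity is violated
  if (length(rp) > 1L) {
    dr <- diff(rp)
    dq <- diff(qp)
    fwd_pair <- strand[-length(strand)] == "+" & strand[-1L] == "+"
    inv_pair <- strand[-length(strand)] == "-" & strand[-1L] == "-"
    ok <- (fwd_pair & dq > 0L & abs(dr - dq) <= indel_tol & dr <= max_gap) |
          (inv_pair & dq < 0L & abs(dr + dq) <= indel_tol & dr <= max_gap)
    block <- cumsum(c(1L, !ok))
  } else block <- 1L

  anchors <- data.frame(rp = rp, qp = qp, strand = strand, block = block)
  bl <- split(anchors, anchors$block)
  bl <- bl[vapply(bl, nrow, 1L) >= min_block_anchors]
  if (length(bl) == 0L)
    stop("no anchor block with at least ", min_block_anchors,
         " anchors; try a smaller k")
  blocks <- do.call(rbind, lapply(bl, function(b) {
    data.frame(ref_start = min(b$rp), ref_end = max(b$rp) + k - 1L,
               q_start = min(b$qp), q_end = max(b$qp) + k - 1L,
               orientation = if (b$strand[1L] == "+") "forward" else "inverted",
               n_anchors = nrow(b))
  }))
  blocks <- blocks[order(blocks$ref_start), ]
  rownames(blocks) <- NULL
  keep_ids <- as.integer(names(bl))
  anchors <- anchors[anchors$block %in% keep_ids, ]
  structure(list(blocks = blocks, anchors = anchors, k = k,
                 ref_len = nchar(r), q_len = nq),
            class = "anchor_chain")
}

#' @export
print.anchor_chain <- function(x, ...) {
  cat(sprintf("anchor_chain: %d block(s), %d anchors (k = %d)\n",
              nrow(x$blocks), nrow(x$anchors), x$k))
  print(x$blocks)
  invisible(x)
}

chain_coverage <- function(chain) {
  b <- chain$blocks
  c(ref = sum(b$ref_end - b$ref_start + 1L) / chain$ref_len,
    query = sum(abs(b$q_end - b$q_start) + 1L) / chain$q_len)
}

## rotate an indel run leftward against the reference until it can shift
## no further (left-alignment in homopolymer/repeat context)
left_normalize <- function(pos, allele, ref_chars, is_ins) {
  len <- nchar(allele)
  if (len == 0L) return(list(pos = pos, allele = allele))
  a <- strsplit(allele, "", fixed = TRUE)[[1]]
  if (is_ins) {
    ## pos = reference base left of the insertion point
    while (pos >= 1L && ref_chars[pos] == a[len]) {
      a <- c(ref_chars[pos], a[-len])
      pos <- pos - 1L
    }
  } else {
    ## pos = first deleted base
    while (pos > 1L && ref_chars[pos - 1L] == a[len]) {
      a <- c(ref_chars[pos - 1L], a[-len])
      pos <- pos - 1L
    }
  }
  list(pos = pos, allele = paste(a, collapse = ""))
}

## emit variant records from one aligned gap pair; offset = ref coordinate
## of the base preceding the gap
emit_from_alignment <- function(ral, qal, offset, ref_chars) {
  rv <- strsplit(ral, "", fixed = TRUE)[[1]]
  qv <- strsplit(qal, "", fixed = TRUE)[[1]]
  n <- length(rv)
  out <- list()
  i <- 1L
  rpos <- offset
  while (i <= n) {
    if (rv[i] != "-" && qv[i] != "-") {
      rpos <- rpos + 1L
      if (rv[i] != qv[i])
        out[[length(out) + 1L]] <- list(pos = rpos, ref = rv[i], alt = qv[i],
                                        type = "SNP")
      i <- i + 1L
    } else if (rv[i] == "-") {
      j <- i
      while (j <= n && rv[j] == "-") j <- j + 1L
      ins <- paste(qv[i:(j - 1L)], collapse = "")
      nrm <- left_normalize(rpos, ins, ref_chars, is_ins = TRUE)
      out[[length(out) + 1L]] <- list(pos = nrm$pos, ref = "", alt = nrm$allele,
                                      type = "INS")
      i <- j
    } else {
      j <- i
      while (j <= n && qv[j] == "-") j <- j + 1L
      del <- paste(rv[i:(j - 1L)], collapse = "")
      nrm <- left_normalize(rpos + 1L, del, ref_chars, is_ins = FALSE)
      out[[length(out) + 1L]] <- list(pos = nrm$pos, ref = nrm$allele, alt = "",
                                      type = "DEL")
      rpos <- rpos + (j - i)
      i <- j
    }
  }
  out
}

nw_align_gap <- function(rs, qs) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(rs),
                                       Biostrings::DNAString(qs),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1)
  list(ref = as.character(Biostrings::alignedPattern(aln)),
       query = as.character(Biostrings::alignedSubject(aln)))
}

#' Call SNP and indel variants between two assemblies
#'
#' Within each forward block of the anchor chain, the unanchored gaps
#' between consecutive anchors are compared: identical gap pairs are
#' skipped, pure insertions/deletions are emitted directly, and differing
#' gap pairs up to `max_align_len` are globally aligned with affine gap
#' penalties (match +1, mismatch -2, gap open 4, gap extend 1). Runs of
#' adjacent substitutions are emitted as separate SNPs unless
#' `merge_mnp = TRUE`. Indels are left-aligned against the reference.
#' Inverted blocks are excluded here and reported by
#' [detect_inversions()].
#'
#' @param ref,query [plastome()]s or DNA strings.
#' @param chain Result of [anchor_align()]; computed if `NULL`.
#' @param max_align_len Longest differing gap pair that will be realigned.
#'   Longer pairs of equal length are compared position-by-position;
#'   longer pairs of unequal length raise an error naming the interval.
#' @param min_coverage Minimum fraction of both genomes the chain must
#'   cover.
#' @param merge_mnp Merge runs of adjacent SNPs into MNP records.
#' @param annotate Attach region/gene/effect columns (needs an annotated
#'   reference plastome).
#' @return A [variant_table()] sorted by reference position.
#' @export
call_variants <- function(ref, query, chain = NULL, max_align_len = 20000L,
                          min_coverage = 0.95, merge_mnp = FALSE,
                          annotate = FALSE) {
  r <- as_sequence(ref)
  q <- as_sequence(query)
  if (is.null(chain)) chain <- anchor_align(r, q)
  ref_chars <- strsplit(r, "", fixed = TRUE)[[1]]
  k <- chain$k

  ## gap jobs: unanchored stretches between consecutive anchors of forward
  ## blocks, plus the unanchored genome ends outside the chain (anchors
  ## cannot reach into the terminal IR copy, whose k-mers are two-copy)
  jobs <- list()
  fwd_ids <- unique(chain$anchors$block[chain$anchors$strand == "+"])
  for (bid in fwd_ids) {
    a <- chain$anchors[chain$anchors$block == bid, ]
    if (nrow(a) < 2L) next
    br <- which(diff(a$rp) != 1L | diff(a$qp) != 1L)
    for (i in br)
      jobs[[length(jobs) + 1L]] <- c(a$rp[i] + k, a$rp[i + 1L] - 1L,
                                     a$qp[i] + k, a$qp[i + 1L] - 1L)
  }
  b <- chain$blocks
  first_b <- b[which.min(b$ref_start), ]
  last_b <- b[which.max(b$ref_end), ]
  term <- 0L
  if (first_b$orientation == "forward" &&
      (first_b$ref_start > 1L || first_b$q_start > 1L)) {
    jobs[[length(jobs) + 1L]] <- c(1L, first_b$ref_start - 1L,
                                   1L, first_b$q_start - 1L)
    term <- term + first_b$ref_start - 1L
  }
  if (last_b$orientation == "forward" &&
      (last_b$ref_end < chain$ref_len || last_b$q_end < chain$q_len)) {
    jobs[[length(jobs) + 1L]] <- c(last_b$ref_end + 1L, chain$ref_len,
                                   last_b$q_end + 1L, chain$q_len)
    term <- term + chain$ref_len - last_b$ref_end
  }
  cov <- chain_coverage(chain) + term / c(chain$ref_len, chain$q_len)
  if (any(cov < min_coverage))
    stop(sprintf("anchor chain covers only %.1f%% of reference and %.1f%% of query (need %.0f%%)",
                 100 * cov[["ref"]], 100 * cov[["query"]], 100 * min_coverage))

  recs <- list()
  for (job in jobs) {
    ref_from <- job[1L]; ref_to <- job[2L]
    q_from <- job[3L]; q_to <- job[4L]
    {
      ## an anchor can reach into an indel when the event's first bases
      ## coincide with the reference continuation; the two anchors then
      ## overlap on one genome. Un-claim the overlap from the left anchor
      ## (its bases match by construction) so no position is lost.
      m <- max(0L, ref_from - ref_to - 1L, q_from - q_to - 1L)
      ref_from <- ref_from - m
      q_from <- q_from - m
      rs <- if (ref_from > ref_to) "" else substr(r, ref_from, ref_to)
      qs <- if (q_from > q_to) "" else substr(q, q_from, q_to)
      if (identical(rs, qs)) next
      offset <- ref_from - 1L   # ref base preceding the gap
      if (nchar(rs) == 0L) {
        nrm <- left_normalize(offset, qs, ref_chars, is_ins = TRUE)
        recs[[length(recs) + 1L]] <- list(list(pos = nrm$pos, ref = "",
                                               alt = nrm$allele, type = "INS"))
      } else if (nchar(qs) == 0L) {
        nrm <- left_normalize(offset + 1L, rs, ref_chars, is_ins = FALSE)
        recs[[length(recs) + 1L]] <- list(list(pos = nrm$pos, ref = nrm$allele,
                                               alt = "", type = "DEL"))
      } else if (nchar(rs) <= max_align_len && nchar(qs) <= max_align_len) {
        aln <- nw_align_gap(rs, qs)
        recs[[length(recs) + 1L]] <- emit_from_alignment(aln$ref, aln$query,
                                                         offset, ref_chars)
      } else if (nchar(rs) == nchar(qs)) {
        ## equal-length long gap (e.g. a diverged IR interior): direct
        ## position-by-position comparison
        rv <- strsplit(rs, "", fixed = TRUE)[[1]]
        qv <- strsplit(qs, "", fixed = TRUE)[[1]]
        d <- which(rv != qv)
        recs[[length(recs) + 1L]] <- lapply(d, function(ii)
          list(pos = offset + ii, ref = rv[ii], alt = qv[ii], type = "SNP"))
      } else {
        stop(sprintf("gap pair at reference %d-%d (%d bp vs %d bp) exceeds max alignable length %d",
                     ref_from, ref_to, nchar(rs), nchar(qs), max_align_len))
      }
    }
  }
  recs <- unlist(recs, recursive = FALSE)
  if (length(recs) == 0L) {
    vt <- variant_table(chrom = if (inherits(ref, "plastome")) ref$id else "ref")
  } else {
    df <- data.frame(pos = vapply(recs, `[[`, 1L, "pos"),
                     ref = vapply(recs, `[[`, "", "ref"),
                     alt = vapply(recs, `[[`, "", "alt"),
                     type = vapply(recs, `[[`, "", "type"))
    df <- df[order(df$pos, df$type), ]
    vt <- variant_table(df$pos, df$ref, df$alt, df$type,
                        chrom = if (inherits(ref, "plastome")) ref$id else "ref")
  }
  if (merge_mnp && nrow(vt) > 1L) vt <- merge_mnps(vt)
  if (annotate && inherits(ref, "plastome")) vt <- annotate_variants(vt, ref)
  vt
}

## collapse runs of adjacent SNPs into MNP records (reporting option; the
## default counts each substitution as its own event)
merge_mnps <- function(vt) {
  is_snp <- vt$type == "SNP"
  grp <- cumsum(c(1L, diff(vt$pos) != 1L | !(is_snp[-1L] & is_snp[-nrow(vt)])))
  merged <- do.call(rbind, lapply(split(seq_len(nrow(vt)), grp), function(idx) {
    if (length(idx) == 1L || !all(vt$type[idx] == "SNP")) return(vt[idx, ])
    data.frame(chrom = vt$chrom[idx[1L]], pos = vt$pos[idx[1L]],
               ref = paste(vt$ref[idx], collapse = ""),
               alt = paste(vt$alt[idx], collapse = ""),
               type = "MNP", region = NA_character_, gene = NA_character_,
               effect = NA_character_)
  }))
  rownames(merged) <- NULL
  class(merged) <- c("variant_table", "data.frame")
  merged
}

#' Apply a variant table to a reference sequence
#'
#' Reconstructs the query sequence implied by a set of SNP/INS/DEL records
#' (used by the round-trip invariant and by the synthetic-data generator).
#'
#' @param ref_seq Reference DNA string.
#' @param variants A [variant_table()].
#' @return The edited sequence.
#' @export
apply_variants <- function(ref_seq, variants) {
  ch <- strsplit(as_sequence(ref_seq), "", fixed = TRUE)[[1]]
  ins_after <- rep("", length(ch) + 1L)   # ins_after[p+1] = inserted after base p
  keep <- rep(TRUE, length(ch))
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (v$type %in% c("SNP", "MNP")) {
        idx <- v$pos:(v$pos + nchar(v$ref) - 1L)
        ch[idx] <- strsplit(v$alt, "", fixed = TRUE)[[1]]
      } else if (v$type == "DEL") {
        keep[v$pos:(v$pos + nchar(v$ref) - 1L)] <- FALSE
      } else if (v$type == "INS") {
        ins_after[v$pos + 1L] <- paste0(ins_after[v$pos + 1L], v$alt)
      }
    }
  }
  pieces <- character(2L * length(ch) + 1L)
  pieces[1L] <- ins_after[1L]
  pieces[seq(2L, 2L * length(ch), by = 2L)] <- ifelse(keep, ch, "")
  pieces[seq(3L, 2L * length(ch) + 1L, by = 2L)] <- ins_after[-1L]
  paste(pieces, collapse = "")
}

#' Detect inversions from an anchor chain
#'
#' Every maximal inverted block becomes one call. For each call the
#' flanking sequence is searched for an inverted-repeat pair (the usual
#' mediator of plastome inversions, e.g. paired tRNA genes) by locally
#' aligning the upstream window against the reverse complement of the
#' downstream window; the repeat is reported with its percent identity
#' when the local alignment is at least `min_repeat_len` long.
#'
#' @param chain An [anchor_align()] result.
#' @param ref Reference sequence (needed for the flanking-repeat search;
#'   optional).
#' @param flank_window Window (bp) searched on both sides of each call.
#' @param min_repeat_len Minimum aligned length for a reported repeat.
#' @return Data frame with one row per inversion: `ref_start`, `ref_end`,
#'   `q_start`, `q_end`, `length`, and when found `repeat_len`,
#'   `repeat_identity` (matches / aligned columns).
#' @export
detect_inversions <- function(chain, ref = NULL, flank_window = 500L,
                              min_repeat_len = 20L) {
  b <- chain$blocks[chain$blocks$orientation == "inverted", , drop = FALSE]
  if (nrow(b) == 0L)
    return(data.frame(ref_start = integer(), ref_end = integer(),
                      q_start = integer(), q_end = integer(),
                      length = integer(), repeat_len = integer(),
                      repeat_identity = numeric()))
  out <- data.frame(ref_start = b$ref_start, ref_end = b$ref_end,
                    q_start = b$q_start, q_end = b$q_end,
                    length = b$ref_end - b$ref_start + 1L,
                    repeat_len = NA_integer_, repeat_identity = NA_real_)
  if (!is.null(ref)) {
    r <- as_sequence(ref)
    n <- nchar(r)
    for (i in seq_len(nrow(out))) {
      s <- out$ref_start[i]; e <- out$ref_end[i]
      up_from <- max(1L, s - flank_window)
      dn_to <- min(n, e + flank_window)
      if (s - 1L < up_from + min_repeat_len - 1L || dn_to - (e + 1L) < min_repeat_len - 1L) next
      up <- substr(r, up_from, s - 1L)
      dn <- substr(r, e + 1L, dn_to)
      mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                      baseOnly = TRUE)
      aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(up),
                                           Biostrings::DNAString(revcomp(dn)),
                                           type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 5, gapExtension = 2)
      w <- Biostrings::nchar(aln)
      if (w >= min_repeat_len) {
        out$repeat_len[i] <- w
        out$repeat_identity[i] <- Biostrings::nmatch(aln) / w
      }
    }
  }
  out
}

#' Classify a genomic position by annotation context
#'
#' A position inside a CDS exon is `CDS`; a position inside a gene's span
#' but in none of its exons is `intron`; everything else (including tRNA
#' and rRNA exons, which are neither protein-coding sequence nor intron)
#' is `intergenic`. The gene symbol is attached for the first two.
#'
#' @param pos Integer vector of 1-based positions.
#' @param p An annotated [plastome()].
#' @return Data frame with columns `region` and `gene`.
#' @export
classify_region <- function(pos, p) {
  stopifnot(inherits(p, "plastome"))
  region <- rep("intergenic", length(pos))
  gene <- rep(NA_character_, length(pos))
  for (f in p$features) {
    span <- feature_span(f)
    in_span <- pos >= span[1L] & pos <= span[2L]
    if (!any(in_span)) next
    in_exon <- rep(FALSE, length(pos))
    for (e in seq_len(nrow(f$exons)))
      in_exon <- in_exon | (pos >= f$exons[e, 1L] & pos <= f$exons[e, 2L])
    if (f$kind == "CDS") {
      hit <- in_exon & region != "CDS"
      region[hit] <- "CDS"; gene[hit] <- f$name
    }
    intronic <- in_span & !in_exon & region == "intergenic"
    region[intronic] <- "intron"; gene[intronic] <- f$name
  }
  data.frame(region = region, gene = gene, stringsAsFactors = FALSE)
}

## exon-joined coding sequence in transcription direction
coding_sequence <- function(f, seq) {
  parts <- vapply(seq_len(nrow(f$exons)), function(e) {
    s <- substr(seq, f$exons[e, 1L], f$exons[e, 2L])
    if (f$strand == "-") revcomp(s) else s
  }, "")
  joined <- paste(parts, collapse = "")
  substr(joined, f$codon_start, nchar(joined))
}

## map a genome position into the 1-based offset along the coding sequence
coding_offset <- function(f, pos) {
  off <- 0L
  for (e in seq_len(nrow(f$exons))) {
    s <- f$exons[e, 1L]; t <- f$exons[e, 2L]
    if (pos >= s && pos <= t) {
      within <- if (f$strand == "+") pos - s + 1L else t - pos + 1L
      return(off + within - (f$codon_start - 1L))
    }
    off <- off + (t - s + 1L)
  }
  NA_integer_
}

translate_codon <- function(codon, first, alt_start_ok) {
  if (first && (codon == "ATG" || (alt_start_ok && codon %in% c("GTG", "ACG"))))
    return("M")
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Annotate the coding effect of a SNP
#'
#' Rebuilds the affected codon in transcription direction (strand-aware,
#' exon-joined, honoring `codon_start` and alternative ACG/GTG initiation
#' at codon 1), translates reference and mutated codon, and reports either
#' `"synonymous"` or an amino-acid change string such as `"P58S"` (the
#' 58th residue changes from Pro to Ser).
#'
#' @param pos 1-based reference position of the substitution.
#' @param ref_allele,alt_allele Single bases (reference strand).
#' @param p An annotated [plastome()].
#' @return Effect string, or `NA` if the position is not in a CDS exon.
#' @export
annotate_effect <- function(pos, ref_allele, alt_allele, p) {
  stopifnot(inherits(p, "plastome"), nchar(ref_allele) == 1L, nchar(alt_allele) == 1L)
  for (f in p$features) {
    if (f$kind != "CDS") next
    in_exon <- any(pos >= f$exons[, 1L] & pos <= f$exons[, 2L])
    if (!in_exon) next
    len <- feature_cds_length(f) - (f$codon_start - 1L)
    if (len %% 3L != 0L && !f$is_pseudo)
      stop("CDS length of '", f$name, "' is not divisible by 3 and the gene is not flagged pseudo")
    off <- coding_offset(f, pos)
    if (is.na(off) || off < 1L) next           # inside trimmed codon_start overhang
    if (f$is_pseudo && off > (len %/% 3L) * 3L) next
    aa_i <- (off - 1L) %/% 3L + 1L
    cpos <- (aa_i - 1L) * 3L + 1L
    cds <- coding_sequence(f, p$sequence)
    codon_ref <- substr(cds, cpos, cpos + 2L)
    within <- off - cpos + 1L
    base_ref <- if (f$strand == "+") ref_allele else comp_chars(ref_allele)
    base_alt <- if (f$strand == "+") alt_allele else comp_chars(alt_allele)
    if (substr(codon_ref, within, within) != base_ref)
      stop(sprintf("reference allele mismatch at %d in '%s': annotation says %s, variant says %s",
                   pos, f$name, substr(codon_ref, within, within), base_ref))
    codon_alt <- codon_ref
    substr(codon_alt, within, within) <- base_alt
    aa_ref <- translate_codon(codon_ref, aa_i == 1L, f$alt_start_ok)
    aa_alt <- translate_codon(codon_alt, aa_i == 1L, f$alt_start_ok)
    if (is.na(aa_ref) || is.na(aa_alt)) return(NA_character_)
    return(if (aa_ref == aa_alt) "synonymous"
           else sprintf("%s%d%s", aa_ref, aa_i, aa_alt))
  }
  NA_character_
}

#' Attach region, gene and effect annotation to a variant table
#'
#' @param vt A [variant_table()].
#' @param p An annotated reference [plastome()].
#' @return The table with `region`, `gene` and (for CDS SNPs) `effect`
#'   filled in.
#' @export
annotate_variants <- function(vt, p) {
  if (nrow(vt) == 0L) return(vt)
  ctx <- classify_region(vt$pos, p)
  vt$region <- ctx$region
  vt$gene <- ctx$gene
  vt$effect <- NA_character_
  idx <- which(vt$type == "SNP" & vt$region == "CDS")
  for (i in idx)
    vt$effect[i] <- annotate_effect(vt$pos[i], vt$ref[i], vt$alt[i], p)
  vt
}

#' Derive the cytotype-diagnostic locus set from a genome pair
#'
#' The SNP subset of [call_variants()], keyed by reference position with
#' both alleles. Indels are excluded: their frequencies cannot be read
#' reliably from base counts.
#'
#' @param genome_a,genome_b [plastome()]s or DNA strings (A is the
#'   reference coordinate system).
#' @param chain Optional precomputed [anchor_align()] chain.
#' @param ... Passed to [call_variants()].
#' @return Data frame of class `diagnostic_locus_set` with columns `pos`,
#'   `allele_a`, `allele_b`, positions strictly increasing.
#' @export
diagnostic_loci <- function(genome_a, genome_b, chain = NULL, ...) {
  vt <- call_variants(genome_a, genome_b, chain = chain, ...)
  snps <- vt[vt$type == "SNP", , drop = FALSE]
  out <- data.frame(pos = snps$pos, allele_a = snps$ref, allele_b = snps$alt,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), ]
  rownames(out) <- NULL
  if (any(out$allele_a == out$allele_b)) stop("diagnostic locus with identical alleles")
  class(out) <- c("diagnostic_locus_set", "data.frame")
  out
}
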