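## Population-level summaries over aligned sample plastomes: sliding-window
## nucleotide diversity, haplotype tabulation, Jukes-Cantor distances and a
## neighbor-joining tree.

#' Construct an alignment matrix
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (gaps `-` allowed).
#' @param excluded Optional two-column matrix of 1-based inclusive
#'   intervals to mask from all diversity computations (e.g. an inversion
#'   region, which is a structural rather than point difference).
#' @return A list of class `alignment_matrix`.
#' @export
alignment_matrix <- function(seqs, excluded = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("aligned sequences must all have the same length")
  if (!is.null(excluded)) {
    if (is.vector(excluded)) excluded <- matrix(excluded, ncol = 2L, byrow = TRUE)
    excluded <- matrix(as.integer(excluded), ncol = 2L)
    if (any(excluded < 1L) || any(excluded > L))
      stop("excluded interval outside alignment bounds")
  }
  structure(list(ids = names(seqs), seqs = toupper(seqs), length = L,
                 excluded = excluded), class = "alignment_matrix")
}

ACGT_RAW <- charToRaw("ACGT")

## logical mask of alignment columns excluded from diversity computations
excluded_mask <- function(m) {
  mask <- rep(FALSE, m$length)
  if (!is.null(m$excluded))
    for (i in seq_len(nrow(m$excluded)))
      mask[m$excluded[i, 1L]:m$excluded[i, 2L]] <- TRUE
  mask
}

#' Pairwise nucleotide diversity between two aligned sequences
#'
#' Mismatches divided by compared sites, where any site carrying a gap or
#' N in either sequence is excluded from both numerator and denominator
#' (pairwise deletion).
#'
#' @param a,b Equal-length aligned DNA strings.
#' @param mask Optional logical vector of sites to exclude.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_pi <- function(a, b, mask = NULL) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  ar <- charToRaw(toupper(a))
  br <- charToRaw(toupper(b))
  valid <- (ar %in% ACGT_RAW) & (br %in% ACGT_RAW)
  if (!is.null(mask)) valid <- valid & !mask
  ncomp <- sum(valid)
  if (ncomp == 0L) stop("no comparable sites between the two sequences")
  sum(valid & (ar != br)) / ncomp
}

#' Sliding-window nucleotide diversity
#'
#' Per window, the diversity is the mean over all unordered sample pairs
#' of [pairwise_pi()] restricted to the window. Windows are laid out from
#' alignment position 1; the trailing partial window is dropped, so the
#' number of windows is `floor((L - window) / step) + 1`. Excluded
#' intervals are masked. The genome-wide mean is computed the same way
#' over the full alignment.
#'
#' @param m An [alignment_matrix()] with at least 2 samples.
#' @param window Window length in alignment columns (default 1200).
#' @param step Step size (default 400).
#' @return A list of class `diversity_profile` with `start`, `end`,
#'   `midpoint`, `pi` per window, plus `window`, `step` and `mean_pi`.
#' @export
sliding_window_pi <- function(m, window = 1200L, step = 400L) {
  stopifnot(inherits(m, "alignment_matrix"))
  if (length(m$ids) < 2L) stop("at least 2 samples required")
  L <- m$length
  if (window > L) stop("window (", window, ") longer than alignment (", L, ")")
  nw <- (L - window) %/% step + 1L
  starts <- 1L + (seq_len(nw) - 1L) * step
  ends <- starts + window - 1L
  mask <- excluded_mask(m)

  raws <- lapply(m$seqs, charToRaw)
  ok <- lapply(raws, function(r) (r %in% ACGT_RAW))
  ns <- length(raws)
  mm_sum <- rep(0, nw)      # sum over pairs of per-window pi
  npair <- 0L
  tot_pi <- 0
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      valid <- ok[[i]] & ok[[j]] & !mask
      mism <- valid & (raws[[i]] != raws[[j]])
      cv <- c(0, cumsum(valid))
      cm <- c(0, cumsum(mism))
      wv <- cv[ends + 1L] - cv[starts]
      wm <- cm[ends + 1L] - cm[starts]
      mm_sum <- mm_sum + ifelse(wv > 0L, wm / wv, 0)
      nv <- cv[L + 1L]
      if (nv == 0L) stop(sprintf("no comparable sites between '%s' and '%s'",
                                 m$ids[i], m$ids[j]))
      tot_pi <- tot_pi + cm[L + 1L] / nv
      npair <- npair + 1L
    }
  }
  structure(list(start = starts, end = ends,
                 midpoint = (starts + ends) / 2,
                 pi = mm_sum / npair, window = as.integer(window),
                 step = as.integer(step), mean_pi = tot_pi / npair),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf("diversity_profile: %d windows of %d bp (step %d), mean pi %.5g, peak %.5g\n",
              length(x$pi), x$window, x$step, x$mean_pi, max(x$pi)))
  invisible(x)
}

#' Tabulate haplotypes from per-sample variant calls
#'
#' All calls must be expressed on one reference coordinate system. Loci
#' are the union of variant keys (position, type, reference allele) over
#' all samples; samples without a call at a locus carry the reference
#' allele. Samples with identical allele vectors collapse into one
#' haplotype.
#'
#' @param variant_sets Named list (one element per sample) of variant
#'   tables or data frames with columns `pos`, `ref`, `alt`, `type`.
#' @param groups Optional named character vector mapping sample ids to
#'   cytotype group labels; enables the per-locus exclusivity flag (the
#'   alternate allele occurs in exactly one group).
#' @return List of class `haplotype_table`: `loci` (with `exclusive` flag
#'   when groups are given), `alleles` (loci x samples character matrix),
#'   `haplotype` (named vector sample -> haplotype id), `counts`
#'   (haplotype sizes), `n_haplotypes`.
#' @export
build_haplotype_table <- function(variant_sets, groups = NULL) {
  stopifnot(is.list(variant_sets), !is.null(names(variant_sets)))
  samples <- names(variant_sets)
  keyed <- lapply(variant_sets, function(v) {
    v <- as.data.frame(v)
    if (nrow(v) == 0L)
      return(data.frame(key = character(), pos = integer(), ref = character(),
                        alt = character(), type = character()))
    key <- paste(v$pos, v$type, v$ref, sep = "|")
    if (anyDuplicated(key))
      stop("conflicting calls at one position within one sample")
    data.frame(key = key, pos = v$pos, ref = v$ref, alt = v$alt, type = v$type,
               stringsAsFactors = FALSE)
  })
  all_loci <- unique(do.call(rbind, c(list(data.frame(key = character(), pos = integer(),
                                                      ref = character(), alt = character(),
                                                      type = character())),
                                      lapply(keyed, function(k) k[, c("key", "pos", "ref", "alt", "type"), drop = FALSE]))))
  dup_key <- duplicated(all_loci$key)    # same locus, different alt alleles collapse to one column
  loci <- all_loci[!dup_key, , drop = FALSE]
  loci <- loci[order(loci$pos, loci$type), , drop = FALSE]
  rownames(loci) <- NULL
  alleles <- matrix(rep(loci$ref, length(samples)), nrow = nrow(loci),
                    ncol = length(samples),
                    dimnames = list(loci$key, samples))
  for (s in samples) {
    k <- keyed[[s]]
    if (nrow(k)) alleles[k$key, s] <- k$alt
  }
  sig <- apply(alleles, 2L, paste, collapse = "\r")
  if (nrow(loci) == 0L) sig <- setNames(rep("", length(samples)), samples)
  first <- !duplicated(sig)
  hap_of_sig <- setNames(sprintf("H%02d", seq_len(sum(first))), sig[first])
  haplotype <- setNames(hap_of_sig[sig], samples)
  counts <- table(haplotype)
  if (!is.null(groups)) {
    loci$exclusive <- vapply(seq_len(nrow(loci)), function(i) {
      carriers <- samples[alleles[i, ] != loci$ref[i]]
      length(unique(groups[carriers])) == 1L
    }, TRUE)
  }
  structure(list(loci = loci, alleles = alleles, haplotype = haplotype,
                 counts = c(counts), n_haplotypes = length(unique(haplotype))),
            class = "haplotype_table")
}

#' Jukes-Cantor distance matrix from an alignment
#'
#' `d = -(3/4) * log(1 - (4/3) * p)` with `p` the pairwise proportion of
#' differing sites from [pairwise_pi()] (excluded intervals masked).
#'
#' @param m An [alignment_matrix()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
jc_distance_matrix <- function(m) {
  stopifnot(inherits(m, "alignment_matrix"))
  mask <- excluded_mask(m)
  ns <- length(m$ids)
  raws <- lapply(m$seqs, charToRaw)
  ok <- lapply(raws, function(r) (r %in% ACGT_RAW) & !mask)
  d <- matrix(0, ns, ns, dimnames = list(m$ids, m$ids))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      valid <- ok[[i]] & ok[[j]]
      ncomp <- sum(valid)
      if (ncomp == 0L)
        stop(sprintf("no comparable sites between '%s' and '%s'",
                     m$ids[i], m$ids[j]))
      p <- sum(valid & (raws[[i]] != raws[[j]])) / ncomp
      if (p >= 0.75)
        stop(sprintf("p-distance %.3f between '%s' and '%s' is >= 0.75; Jukes-Cantor undefined",
                     p, m$ids[i], m$ids[j]))
      d[i, j] <- d[j, i] <- -0.75 * log(1 - (4 / 3) * p)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Taxa are ordered lexicographically before tree construction so that
#' ties are broken deterministically. On additive distances NJ recovers
#' the generating tree exactly.
#'
#' @param d Symmetric distance matrix with zero diagonal and row/column
#'   names.
#' @param outgroup Optional taxon id to root the tree at.
#' @return A newick string (with branch lengths).
#' @export
nj_tree <- function(d, outgroup = NULL) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix must have row/column names")
  if (!isSymmetric(unname(d), tol = 1e-9)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(d)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("outgroup '", outgroup, "' not among taxa")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  ape::write.tree(tr)
}

#' Does a tree contain a given bipartition?
#'
#' Checks whether some edge of the (unrooted) tree splits the taxa into
#' `group` versus the rest - e.g. whether the two cytotypes form two
#' clades.
#'
#' @param newick Newick string.
#' @param group Character vector of tip labels on one side of the split.
#' @return Logical.
#' @export
has_bipartition <- function(newick, group) {
  tr <- ape::unroot(ape::read.tree(text = newick))
  tips <- tr$tip.label
  group <- sort(intersect(group, tips))
  if (length(group) == 0L || length(group) == length(tips)) return(TRUE)
  parts <- ape::prop.part(tr)
  for (p in parts) {
    side <- sort(tips[p])
    other <- sort(setdiff(tips, side))
    if (identical(side, group) || identical(other, group)) return(TRUE)
  }
  ## prop.part lists clades of the rooted representation; also check
  ## splits induced by single tips
  any(vapply(tips, function(t) identical(group, t), TRUE))
}
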