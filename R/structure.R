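## Quadripartite architecture detection.
##
## Plastomes carry two inverted repeats (IRa/IRb) that are exact
## reverse-complement copies separating the large and small single-copy
## regions. The detector finds the maximal-length pair of disjoint exact
## reverse-complement repeats by k-mer seeding against the reverse
## complement of the genome: a repeat pair shows up as a run of seed
## matches on one anti-diagonal, so maximal exact repeats are recovered in
## near-linear time. Circularity is honored by extending candidate arms
## across the linearization origin.

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Detect the LSC/IRa/SSC/IRb quadripartite structure
#'
#' Finds the maximal pair of disjoint reverse-complement repeats of length
#' at least `min_ir_len` and the two single-copy regions between them. The
#' longer single-copy region is reported as the LSC, the shorter as the
#' SSC; IRa is the repeat copy that is followed (in genome order, wrapping)
#' by the SSC. When two maximal pairs tie, the pair minimizing the SSC
#' length is chosen. Absence of a qualifying repeat is signaled with
#' `found = FALSE`, never an error.
#'
#' Repeats are required to be exact by default (`max_mismatch = 0`);
#' the two IR copies of a plastome are essentially invariant, and exactness
#' keeps the search fast. A small mismatch tolerance can be allowed, in
#' which case seed runs on the same anti-diagonal separated by up to
#' `max_mismatch` substitutions are merged.
#'
#' @param p A [plastome()] or DNA string.
#' @param min_ir_len Minimum repeat arm length in bp.
#' @param max_mismatch Number of substitutions tolerated inside an arm.
#' @param k Seed length (internal; must be < `min_ir_len`).
#' @return A list of class `quadripartite_structure` with elements `found`,
#'   `lsc`, `ira`, `ssc`, `irb` (1-based inclusive intervals; `start > end`
#'   marks wrap-around through the origin) and `lengths` (named vector with
#'   `lsc`, `ssc`, `ir`, `genome`).
#' @export
detect_quadripartite <- function(p, min_ir_len = 10000L, max_mismatch = 0L,
                                 k = 31L) {
  seq <- as_sequence(p)
  circular <- !inherits(p, "plastome") || p$circular
  n <- nchar(seq)
  empty <- structure(list(found = FALSE, lsc = NULL, ira = NULL, ssc = NULL,
                          irb = NULL, lengths = NULL),
                     class = "quadripartite_structure")
  if (n < 2L * min_ir_len + 2L || n < k) return(empty)

  rc <- revcomp(seq)
  ks <- kmer_starts(seq, k)
  kr <- kmer_starts(rc, k)
  keep <- !grepl("N", ks, fixed = TRUE)
  dt_s <- data.table::data.table(kmer = ks[keep], p = which(keep))
  keep_r <- !grepl("N", kr, fixed = TRUE)
  dt_r <- data.table::data.table(kmer = kr[keep_r], j = which(keep_r))
  hits <- dt_s[dt_r, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(empty)

  ## a reverse-complement repeat pair appears as a run of matches between
  ## S and revcomp(S) with constant offset d = p - j; consecutive p on one
  ## diagonal extend one repeat arm
  hits[, d := p - j]
  data.table::setorder(hits, d, p)
  hits[, run := cumsum(c(1L, diff(p) != 1L | diff(d) != 0L))]
  runs <- hits[, .(d = d[1L], p1 = min(p), p2 = max(p)), by = run]
  if (max_mismatch > 0L) {
    ## merge runs on the same diagonal if the unmatched span between them
    ## is at most max_mismatch substitutions
    data.table::setorder(runs, d, p1)
    gap_mm <- c(Inf, runs$p1[-1L] - runs$p2[-nrow(runs)] - k)
    gap_mm[c(TRUE, runs$d[-1L] != runs$d[-nrow(runs)])] <- Inf
    runs[, grp := cumsum(gap_mm > max_mismatch)]
    runs <- runs[, .(d = d[1L], p1 = min(p1), p2 = max(p2)), by = grp]
  }
  ## arm1 on S: [p1, p2 + k - 1]; arm2 (original coordinates) is the
  ## reverse-complement image: j = p - d maps to a = n - j - k + 2
  arms <- data.table::data.table(
    s1 = runs$p1, e1 = runs$p2 + k - 1L,
    s2 = n + runs$d - runs$p2 - k + 2L, e2 = n + runs$d - runs$p1 + 1L)
  arms[, len := e1 - s1 + 1L]
  ## canonical order, disjoint arms only (drop the symmetric duplicate and
  ## self-overlapping palindromic hits)
  arms <- arms[s1 < s2 & e1 < s2]
  if (nrow(arms) == 0L) return(empty)

  if (circular) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    at <- function(i) ch[((i - 1L) %% n) + 1L]
    for (r in seq_len(nrow(arms))) {
      a1 <- arms$s1[r]; b1 <- arms$e1[r]; a2 <- arms$s2[r]; b2 <- arms$e2[r]
      ## grow left end of arm1 with right end of arm2
      while (((a2 - b1 - 1L) %% n) > 0L && ((a1 - b2 - 2L) %% n) > 0L &&
             at(a1 - 1L) == comp_chars(at(b2 + 1L))) {
        a1 <- a1 - 1L; b2 <- b2 + 1L
      }
      ## grow right end of arm1 with left end of arm2
      while (((a2 - b1 - 2L) %% n) > 0L && ((a1 - b2 - 1L) %% n) > 0L &&
             at(b1 + 1L) == comp_chars(at(a2 - 1L))) {
        b1 <- b1 + 1L; a2 <- a2 - 1L
      }
      data.table::set(arms, i = r, j = c("s1", "e1", "s2", "e2", "len"),
                      value = list(a1, b1, a2, b2, b1 - a1 + 1L))
    }
    arms <- unique(arms)
  }
  arms <- arms[len >= min_ir_len]
  if (nrow(arms) == 0L) return(empty)

  ## gaps between the arms, going around the circle
  arms[, gap12 := (s2 - e1 - 1L) %% n]   # after arm1, before arm2
  arms[, gap21 := (s1 - e2 - 1L) %% n]   # after arm2, wrapping to arm1
  arms[, ssc_len := pmin(gap12, gap21)]
  data.table::setorder(arms, -len, ssc_len, s1)
  best <- arms[1L]

  norm1 <- function(i) as.integer(((i - 1L) %% n) + 1L)
  iv <- function(s, e) c(start = norm1(s), end = norm1(e))
  if (best$gap12 <= best$gap21) {
    ira <- iv(best$s1, best$e1); irb <- iv(best$s2, best$e2)
    ssc <- iv(best$e1 + 1L, best$s2 - 1L)
    lsc <- iv(best$e2 + 1L, best$s1 - 1L)
    ssc_len <- best$gap12; lsc_len <- best$gap21
  } else {
    ira <- iv(best$s2, best$e2); irb <- iv(best$s1, best$e1)
    ssc <- iv(best$e2 + 1L, best$s1 - 1L)
    lsc <- iv(best$e1 + 1L, best$s2 - 1L)
    ssc_len <- best$gap21; lsc_len <- best$gap12
  }
  structure(list(found = TRUE, lsc = lsc, ira = ira, ssc = ssc, irb = irb,
                 lengths = c(lsc = as.integer(lsc_len),
                             ssc = as.integer(ssc_len),
                             ir = as.integer(best$len),
                             genome = as.integer(n))),
            class = "quadripartite_structure")
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  if (!x$found) {
    cat("quadripartite structure: not found\n")
  } else {
    l <- x$lengths
    cat(sprintf("quadripartite structure: LSC %d / IRa %d / SSC %d / IRb %d (genome %d bp)\n",
                l[["lsc"]], l[["ir"]], l[["ssc"]], l[["ir"]], l[["genome"]]))
  }
  invisible(x)
}

#' GC content of a plastome
#'
#' Computed as (G+C)/(A+C+G+T); N positions are excluded from both
#' numerator and denominator.
#'
#' @param p A [plastome()] or DNA string.
#' @return Fraction in `[0, 1]`. Use [gc_percent()] for the conventional
#'   two-decimal percent.
#' @export
gc_content <- function(p) {
  seq <- as_sequence(p)
  counts <- table(factor(strsplit(seq, "", fixed = TRUE)[[1]],
                         levels = VALID_BASES))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) stop("sequence contains no unambiguous bases")
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' @rdname gc_content
#' @export
gc_percent <- function(p) round(100 * gc_content(p), 2L)
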