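## MISA-semantics microsatellite scanning.
##
## An SSR is a maximal perfect tandem repeat of a 1-6 bp unit whose repeat
## count reaches the per-unit-length threshold. A repeat qualifying under
## two unit lengths (poly-A as both mono and "AA" di) is reported only at
## its minimal period. SSRs separated by at most `compound_max_gap` bp are
## merged into one compound SSR that counts once in totals.

#' SSR search configuration
#'
#' @param min_repeats Integer vector of length 6: minimum number of
#'   complete repeat units for mono- through hexanucleotide motifs.
#'   Defaults to the conventional MISA plastome setting 10, 6, 5, 5, 5, 5.
#' @param compound_max_gap Two SSRs at most this many bp apart merge into
#'   one compound SSR.
#' @return A list of class `ssr_config`.
#' @export
ssr_config <- function(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                       compound_max_gap = 100L) {
  stopifnot(length(min_repeats) == 6L, all(min_repeats >= 1L),
            compound_max_gap >= 0L)
  structure(list(min_repeats = as.integer(min_repeats),
                 compound_max_gap = as.integer(compound_max_gap)),
            class = "ssr_config")
}

## is `unit` primitive, i.e. not itself a repetition of a shorter unit?
is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (strrep(substr(unit, 1L, d), u %/% d) == unit) return(FALSE)
  }
  TRUE
}

#' Find microsatellites (SSRs) in a sequence
#'
#' Reports all maximal perfect tandem repeats with a primitive unit of
#' 1-6 bp meeting the repeat-count threshold for that unit length, then
#' merges runs separated by at most `cfg$compound_max_gap` bp into
#' compound SSRs. The reported end of a simple SSR covers complete units
#' only (`end - start + 1 = unit_len * n_repeats`). Units containing N are
#' skipped.
#'
#' @param p A [plastome()] or DNA string.
#' @param cfg An [ssr_config()].
#' @return Data frame with columns `start`, `end`, `motif` (the unit as it
#'   occurs; for compound SSRs the units joined by `+`), `unit_len` (`NA`
#'   for compound), `n_repeats` (`NA` for compound), `kind`
#'   (`simple`/`compound`), `n_parts`; sorted by start.
#' @export
find_ssrs <- function(p, cfg = ssr_config()) {
  seq <- as_sequence(p)
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  simple <- list()
  for (u in 1:6) {
    if (n < u * cfg$min_repeats[u]) next
    eq <- ch[seq_len(n - u)] == ch[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values & r$lengths + u >= u * cfg$min_repeats[u])
    for (i in idx) {
      span_start <- starts[i]
      span_len <- r$lengths[i] + u          # maximal period-u span
      n_rep <- span_len %/% u
      if (n_rep < cfg$min_repeats[u]) next
      unit <- substr(seq, span_start, span_start + u - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      if (!is_primitive_unit(unit)) next
      simple[[length(simple) + 1L]] <- data.frame(
        start = span_start, end = span_start + u * n_rep - 1L,
        motif = unit, unit_len = u, n_repeats = n_rep)
    }
  }
  if (length(simple) == 0L)
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit_len = integer(), n_repeats = integer(),
                      kind = character(), n_parts = integer()))
  ssrs <- do.call(rbind, simple)
  ssrs <- ssrs[order(ssrs$start, ssrs$end), ]
  ## merge into compound SSRs: gap between consecutive runs <= max gap
  gap <- c(Inf, ssrs$start[-1L] - cummax(ssrs$end)[-nrow(ssrs)] - 1L)
  grp <- cumsum(gap > cfg$compound_max_gap)
  out <- do.call(rbind, lapply(split(ssrs, grp), function(g) {
    if (nrow(g) == 1L)
      return(data.frame(g, kind = "simple", n_parts = 1L))
    data.frame(start = min(g$start), end = max(g$end),
               motif = paste(g$motif, collapse = "+"),
               unit_len = NA_integer_, n_repeats = NA_integer_,
               kind = "compound", n_parts = nrow(g))
  }))
  rownames(out) <- NULL
  out[order(out$start), ]
}

#' Classify SSRs by genomic context
#'
#' Each SSR is assigned by its start coordinate using the same semantics
#' as [classify_region()]; the counts always sum to the number of SSRs.
#'
#' @param ssrs Result of [find_ssrs()].
#' @param p An annotated [plastome()].
#' @return List with `table` (the SSRs plus `location` and `gene` columns)
#'   and `counts` (named vector over CDS/intron/intergenic).
#' @export
classify_ssr_locations <- function(ssrs, p) {
  ctx <- classify_region(ssrs$start, p)
  ssrs$location <- ctx$region
  ssrs$gene <- ctx$gene
  counts <- table(factor(ssrs$location, levels = c("CDS", "intron", "intergenic")))
  list(table = ssrs, counts = c(counts))
}

#' Summarize an SSR table the way plastome surveys report it
#'
#' @param ssrs Result of [find_ssrs()].
#' @return List with `total`, `n_compound`, counts of simple SSRs by unit
#'   length, and `frac_at_mono` (fraction of all SSRs that are A or T
#'   mononucleotide runs).
#' @export
summarize_ssrs <- function(ssrs) {
  simple <- ssrs[ssrs$kind == "simple", , drop = FALSE]
  by_unit <- table(factor(simple$unit_len, levels = 1:6))
  at_mono <- sum(simple$unit_len == 1L & simple$motif %in% c("A", "T"))
  list(total = nrow(ssrs), n_compound = sum(ssrs$kind == "compound"),
       by_unit_len = c(by_unit), frac_at_mono = at_mono / nrow(ssrs))
}
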