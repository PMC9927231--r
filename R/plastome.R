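#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rbinom rmultinom runif setNames
#' @importFrom utils head tail read.delim write.table
NULL

## let data.table's [ dispatch see this namespace as data.table-aware
.datatable.aware <- TRUE

VALID_BASES <- c("A", "C", "G", "T", "N")

## --- small sequence helpers (character-vector world; Biostrings does the
## --- biochemistry, these keep coordinates honest) ---------------------------

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over A/C/G/T/N.
#' @return The reverse complement, as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## complement without reversal, vectorised over single characters
comp_chars <- function(ch) {
  chartr("ACGTN", "TGCAN", ch)
}

## substring that understands circular wrap-around (1-based inclusive)
subseq_circular <- function(seq, start, end) {
  n <- nchar(seq)
  if (start >= 1 && end <= n && start <= end) return(substr(seq, start, end))
  idx <- ((seq.int(start, end) - 1L) %% n) + 1L
  paste0(strsplit(seq, "", fixed = TRUE)[[1]][idx], collapse = "")
}

rotate_seq <- function(seq, offset) {
  n <- nchar(seq)
  offset <- ((offset - 1L) %% n) + 1L
  if (offset == 1L) return(seq)
  paste0(substr(seq, offset, n), substr(seq, 1L, offset - 1L))
}

#' Construct a gene feature
#'
#' A feature is one annotated gene-like element of a plastome: a protein
#' coding sequence, tRNA, rRNA, intron-bearing gene or pseudogene. Exons are
#' stored as 1-based inclusive intervals ordered in transcription direction
#' (for minus-strand features the first exon is the one with the largest
#' coordinates).
#'
#' @param name Gene symbol (e.g. `"atpI"`).
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"intron"`, `"pseudogene"`.
#' @param strand `"+"` or `"-"`.
#' @param exons A two-column matrix (start, end) of 1-based inclusive
#'   intervals, ordered in transcription direction.
#' @param is_pseudo Logical; pseudogenes are exempt from the frame rule.
#' @param alt_start_ok Logical; `TRUE` for genes with an alternative ACG/GTG
#'   initiation codon (plastids C-to-U edit ACG to AUG, and GTG starts occur
#'   in e.g. rps19).
#' @param codon_start Offset (1, 2 or 3) of the first complete codon,
#'   GenBank `/codon_start` semantics.
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(name, kind = c("CDS", "tRNA", "rRNA", "intron", "pseudogene"),
                         strand = "+", exons, is_pseudo = FALSE,
                         alt_start_ok = FALSE, codon_start = 1L) {
  kind <- match.arg(kind)
  stopifnot(strand %in% c("+", "-"))
  if (is.vector(exons) && !is.matrix(exons)) exons <- matrix(exons, ncol = 2L, byrow = TRUE)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 1L] > exons[, 2L]))
    stop("exon start > end in feature '", name, "'")
  structure(list(name = name, kind = kind, strand = strand, exons = exons,
                 is_pseudo = isTRUE(is_pseudo), alt_start_ok = isTRUE(alt_start_ok),
                 codon_start = as.integer(codon_start)),
            class = "gene_feature")
}

feature_span <- function(f) range(f$exons)

feature_cds_length <- function(f) sum(f$exons[, 2L] - f$exons[, 1L] + 1L)

#' Construct a plastome
#'
#' The central container: one chloroplast genome sequence with annotation
#' and, optionally, its detected quadripartite structure. Sequences are
#' upper-cased and validated against the A/C/G/T/N alphabet; other IUPAC
#' ambiguity codes are rejected so that problems surface at parse time.
#'
#' @param id Accession-like identifier.
#' @param sequence DNA string over A/C/G/T/N (any case).
#' @param circular Logical; plastomes are circular molecules deposited
#'   linearized at a fixed origin.
#' @param features List of [gene_feature()] objects.
#' @param structure Optional result of [detect_quadripartite()].
#' @return An object of class `plastome`.
#' @export
plastome <- function(id, sequence, circular = TRUE, features = list(),
                     structure = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence for plastome '", id, "'")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L)
    stop("sequence of '", id, "' contains characters outside A/C/G/T/N: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  for (f in features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature objects")
    if (any(f$exons < 1L) || any(f$exons > n))
      stop("feature '", f$name, "' has exons outside [1, ", n, "]")
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 features = features, structure = structure),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("plastome '%s': %s bp, %s, %d features\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", length(x$features)))
  if (!is.null(x$structure) && isTRUE(x$structure$found)) {
    s <- x$structure
    cat(sprintf("  LSC %d bp / IR %d bp / SSC %d bp\n",
                s$lengths[["lsc"]], s$lengths[["ir"]], s$lengths[["ssc"]]))
  }
  invisible(x)
}

#' @export
length.plastome <- function(x) nchar(x$sequence)

## accept either a plastome or a bare character sequence
as_sequence <- function(x) {
  if (inherits(x, "plastome")) x$sequence
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a plastome or a single DNA string")
}

## deterministic local RNG scope: evaluates expr under a seed and restores
## the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
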