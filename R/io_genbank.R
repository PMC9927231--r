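## GenBank flat-file reading/writing.
##
## Only the slice of the format that plastome records use is supported:
## LOCUS topology, gene/CDS/tRNA/rRNA features with join()/complement()
## locations, /gene, /codon_start, /pseudo and /note qualifiers, and the
## ORIGIN sequence block. Parsing is insensitive to sequence-line wrap width
## and case. All on-disk coordinates are 1-based inclusive; this module is
## the only place where coordinate conventions are converted.

parse_location <- function(loc, lineno) {
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (any(grepl("^complement\\(", parts))) {
    if (!all(grepl("^complement\\(", parts)))
      stop("mixed-strand join location at line ", lineno)
    strand <- "-"
    parts <- sub("^complement\\((.*)\\)$", "\\1", parts)
  }
  ivs <- lapply(parts, function(p) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      rep(as.integer(p), 2L)
    } else stop("malformed location '", p, "' at line ", lineno)
  })
  exons <- do.call(rbind, ivs)
  ## store exons in transcription direction
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  list(strand = strand, exons = exons)
}

#' Read a plastome from a GenBank flat file
#'
#' Parses the LOCUS line (length, circular/linear topology), the feature
#' table (gene, CDS, tRNA and rRNA records, with multi-exon join locations
#' collapsed into one feature) and the ORIGIN sequence block. Features
#' carrying `/pseudo` are flagged as pseudogenes; a `/note` mentioning an
#' alternative start lets [annotate_effect()] accept ACG/GTG initiation.
#'
#' @param path Path to a GenBank flat file.
#' @return A [plastome()].
#' @seealso [write_genbank()] for the inverse (round trips are lossless for
#'   every field the plastome type defines).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty GenBank file: ", path)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("no LOCUS line in ", path)
  locus <- strsplit(trimws(lines[locus_i[1L]]), "[[:space:]]+")[[1]]
  id <- locus[2L]
  circular <- any(tolower(locus) == "circular")

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) stop("no ORIGIN block in ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[seq.int(origin_i[1L] + 1L, end_i - 1L)]
  sequence <- toupper(gsub("[0-9[:space:]]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("missing sequence in ", path)

  feat_i <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_i)) {
    block <- lines[seq.int(feat_i[1L] + 1L, origin_i[1L] - 1L)]
    linenos <- seq.int(feat_i[1L] + 1L, origin_i[1L] - 1L)
    ## entries start at column 6; continuations/qualifiers at column 22
    starts <- which(grepl("^ {5}[A-Za-z]", block))
    raw_feats <- list()
    for (j in seq_along(starts)) {
      from <- starts[j]
      to <- if (j < length(starts)) starts[j + 1L] - 1L else length(block)
      entry <- block[from:to]
      key <- sub("^ {5}([^ ]+).*$", "\\1", entry[1L])
      rest <- trimws(sub("^ {5}[^ ]+", "", entry[1L]))
      cont <- entry[-1L]
      ## location may continue over lines until the first qualifier
      qual_start <- grep("^ +/", cont)
      loc_extra <- if (length(qual_start)) head(cont, qual_start[1L] - 1L) else cont
      loc <- paste0(rest, paste(trimws(loc_extra), collapse = ""))
      quals <- if (length(qual_start)) trimws(cont[qual_start[1L]:length(cont)]) else character()
      raw_feats[[j]] <- list(key = key, loc = loc, quals = quals,
                             lineno = linenos[from])
    }
    get_qual <- function(quals, name) {
      hit <- grep(paste0("^/", name, "(=|$)"), quals, value = TRUE)
      if (length(hit) == 0L) return(NULL)
      v <- sub(paste0("^/", name, "=?"), "", hit[1L])
      gsub('^"|"$', "", v)
    }
    for (rf in raw_feats) {
      if (!rf$key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      pseudo <- any(grepl("^/pseudo$", rf$quals))
      if (rf$key == "gene" && !pseudo) next   # plain gene envelopes duplicate CDS/tRNA/rRNA
      loc <- parse_location(rf$loc, rf$lineno)
      name <- get_qual(rf$quals, "gene")
      if (is.null(name)) name <- get_qual(rf$quals, "locus_tag")
      if (is.null(name)) name <- paste0(rf$key, "_", loc$exons[1L, 1L])
      cs <- get_qual(rf$quals, "codon_start")
      note <- get_qual(rf$quals, "note")
      kind <- if (rf$key == "gene") "pseudogene" else rf$key
      features[[length(features) + 1L]] <- gene_feature(
        name = name, kind = kind, strand = loc$strand, exons = loc$exons,
        is_pseudo = pseudo,
        alt_start_ok = !is.null(note) && grepl("alternative start", note, ignore.case = TRUE),
        codon_start = if (is.null(cs)) 1L else as.integer(cs))
    }
  }
  plastome(id = id, sequence = sequence, circular = circular, features = features)
}

format_location <- function(f) {
  exons <- f$exons
  if (f$strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  ivs <- apply(exons, 1L, function(iv)
    if (iv[1L] == iv[2L]) as.character(iv[1L]) else paste0(iv[1L], "..", iv[2L]))
  loc <- if (length(ivs) > 1L) paste0("join(", paste(ivs, collapse = ","), ")") else ivs
  if (f$strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

#' Write a plastome as a GenBank flat file
#'
#' @param p A [plastome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(p, path) {
  stopifnot(inherits(p, "plastome"))
  n <- nchar(p$sequence)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                   p$id, n, if (p$circular) "circular" else "linear",
                   format(Sys.Date(), "%d-%b-%Y")),
           sprintf("DEFINITION  %s plastome.", p$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  for (f in p$features) {
    key <- if (f$kind == "pseudogene") "gene" else f$kind
    out <- c(out, sprintf("     %-16s%s", key, format_location(f)),
             sprintf("                     /gene=\"%s\"", f$name))
    if (f$codon_start != 1L)
      out <- c(out, sprintf("                     /codon_start=%d", f$codon_start))
    if (f$is_pseudo || f$kind == "pseudogene")
      out <- c(out, "                     /pseudo")
    if (f$alt_start_ok)
      out <- c(out, "                     /note=\"alternative start codon\"")
  }
  out <- c(out, "ORIGIN")
  s <- tolower(p$sequence)
  for (i in seq(1L, n, by = 60L)) {
    chunk <- substr(s, i, min(i + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", i, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read DNA sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector, or a single [plastome()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "plastome")) seqs <- setNames(seqs$sequence, seqs$id)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}
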