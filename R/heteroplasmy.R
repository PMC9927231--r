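## Heteroplasmy quantification from filtered base counts.
##
## A mixed-cytotype individual carries the alternate cytotype's alleles at
## the diagnostic loci at a roughly constant low frequency genome-wide,
## while nuclear or mitochondrial copies of plastid DNA (NUMT/mtpt) mimic
## that signal only at the loci they cover and only at the other
## compartment's sequencing depth. The estimator therefore (i) keeps only
## high-quality, both-strand base counts, (ii) summarizes the per-locus
## minor-type frequency with its median across the diagnostic loci,
## (iii) requires the minor allele to be visible at nearly all loci, and
## (iv) applies a depth-ratio guard comparing the minor-allele depth with
## the nuclear depth.

#' Heteroplasmy-calling configuration
#'
#' @param min_phred Reads at or below this Phred score are discarded
#'   (strictly greater than `min_phred` passes).
#' @param require_both_strands Drop an allele at a locus unless it is seen
#'   on both strands.
#' @param het_cutoff Minimum summary minor frequency to call heteroplasmy
#'   (the conventional 2% screening cutoff).
#' @param numt_ratio_threshold Minimum minor-depth / nuclear-depth ratio;
#'   below it the minor signal could be a homologous insert sequenced at
#'   organismal depth.
#' @param consistency_fraction Minimum fraction of usable loci at which
#'   the minor allele must reach `het_cutoff`: genome-wide heteroplasmy
#'   shows the minor type almost everywhere, unlike locus-sporadic
#'   heterogeneity.
#' @param mt_insert_mask Optional two-column matrix of intervals (1-based,
#'   inclusive) covering known mitochondrial/nuclear plastid-DNA inserts;
#'   diagnostic loci inside are excluded.
#' @return A list of class `heteroplasmy_config`.
#' @export
heteroplasmy_config <- function(min_phred = 20, require_both_strands = TRUE,
                                het_cutoff = 0.02, numt_ratio_threshold = 3.0,
                                consistency_fraction = 0.9,
                                mt_insert_mask = NULL) {
  stopifnot(het_cutoff > 0, het_cutoff < 0.5, numt_ratio_threshold > 0,
            consistency_fraction >= 0, consistency_fraction <= 1)
  if (!is.null(mt_insert_mask))
    mt_insert_mask <- matrix(as.integer(mt_insert_mask), ncol = 2L)
  structure(list(min_phred = min_phred,
                 require_both_strands = isTRUE(require_both_strands),
                 het_cutoff = het_cutoff,
                 numt_ratio_threshold = numt_ratio_threshold,
                 consistency_fraction = consistency_fraction,
                 mt_insert_mask = mt_insert_mask),
            class = "heteroplasmy_config")
}

#' Quality- and strand-filter a base-count profile
#'
#' Removes reads failing the Phred filter (counts carried by the
#' simulator's `qual_fail` table; profiles read from disk already store
#' passing counts only) and, at each locus, zeroes both strand counts of
#' any allele observed on only one strand. Depth is recomputed.
#'
#' @param profile A [base_count_profile()].
#' @param cfg A [heteroplasmy_config()].
#' @return The filtered profile (`filtered = TRUE`).
#' @export
filter_basecounts <- function(profile, cfg = heteroplasmy_config()) {
  stopifnot(inherits(profile, "base_count_profile"))
  d <- profile$data
  if (!is.null(profile$qual_fail))
    d[, BC_COUNT_COLS] <- d[, BC_COUNT_COLS] - profile$qual_fail[, BC_COUNT_COLS]
  if (any(d[, BC_COUNT_COLS] < 0))
    stop("quality-failing counts exceed totals")
  if (cfg$require_both_strands) {
    for (al in c("A", "C", "G", "T", "ins", "del")) {
      f <- d[[paste0(al, "_f")]]
      r <- d[[paste0(al, "_r")]]
      bias <- (f == 0L) != (r == 0L)
      d[[paste0(al, "_f")]][bias] <- 0L
      d[[paste0(al, "_r")]][bias] <- 0L
    }
  }
  d$depth <- rowSums(d[, BC_DEPTH_COLS])
  out <- profile
  out$data <- d
  out$qual_fail <- NULL
  out$filtered <- TRUE
  out
}

## count of one specific allele per row (rows and alleles aligned)
counts_at <- function(d, alleles) {
  idx <- cbind(seq_len(nrow(d)), match(alleles, c("A", "C", "G", "T")))
  f <- as.matrix(d[, c("A_f", "C_f", "G_f", "T_f")])
  r <- as.matrix(d[, c("A_r", "C_r", "G_r", "T_r")])
  f[idx] + r[idx]
}

#' Classify the major cytotype of a sample
#'
#' At each usable diagnostic locus the type whose allele holds the count
#' majority wins the locus; the sample's major type is the type winning
#' more than half of the usable loci.
#'
#' @param profile A (preferably filtered) [base_count_profile()].
#' @param loci A [diagnostic_loci()] set.
#' @param labels Length-2 labels for the allele_a / allele_b types.
#' @param min_loci Minimum number of diagnostic loci with coverage.
#' @return One of `labels`; a tie or insufficient loci is an error.
#' @export
classify_major_type <- function(profile, loci, labels = c("Type 1", "Type 2"),
                                min_loci = 10L) {
  d <- profile$data[match(loci$pos, profile$data$pos), , drop = FALSE]
  usable <- !is.na(d$pos) & d$depth > 0
  if (sum(usable) < min_loci)
    stop("only ", sum(usable), " diagnostic loci with coverage; need at least ", min_loci)
  d <- d[usable, , drop = FALSE]
  ca <- counts_at(d, loci$allele_a[usable])
  cb <- counts_at(d, loci$allele_b[usable])
  wins_a <- sum(ca > cb)
  wins_b <- sum(cb > ca)
  if (wins_a == wins_b) stop("tie: equal numbers of loci favor each type")
  if (wins_a > wins_b) labels[1L] else labels[2L]
}

#' Estimate the minor-cytotype fraction of a sample
#'
#' Per usable diagnostic locus, the minor-type frequency is the count of
#' the minor type's allele divided by the locus depth after filtering.
#' The summary statistic is the median across loci (robust to the few
#' loci disturbed by organellar-insert homology); the mean is reported
#' alongside. The verdict is `heteroplasmy` when the summary reaches
#' `het_cutoff` and the minor allele is genome-wide consistent, i.e.
#' visible at a frequency of at least half the cutoff at
#' `consistency_fraction` of the loci; a mixture sitting exactly at the
#' cutoff keeps roughly half its loci below the cutoff by binomial noise
#' alone, so consistency is judged at `het_cutoff / 2` while the reported
#' `fraction_of_loci_supporting` counts loci at the full cutoff.
#' Otherwise the verdict is `below_cutoff`; [numt_guard()] may downgrade
#' a positive call to `ambiguous`. Loci inside `cfg$mt_insert_mask` are
#' excluded.
#'
#' @param profile A filtered [base_count_profile()].
#' @param loci A [diagnostic_loci()] set.
#' @param cfg A [heteroplasmy_config()].
#' @param major_type Optional precomputed [classify_major_type()] result.
#' @param labels Type labels (allele_a's type first).
#' @return A list of class `heteroplasmy_call`: `sample_id`, `major_type`,
#'   `minor_type`, `per_locus` (pos, minor frequency, depth),
#'   `minor_fraction` (median), `minor_fraction_mean`,
#'   `fraction_of_loci_supporting`, `minor_mean_depth`, `nuclear_depth`,
#'   `n_usable_loci`, `verdict`.
#' @export
estimate_minor_fraction <- function(profile, loci, cfg = heteroplasmy_config(),
                                    major_type = NULL,
                                    labels = c("Type 1", "Type 2")) {
  stopifnot(inherits(profile, "base_count_profile"))
  if (is.null(major_type))
    major_type <- classify_major_type(profile, loci, labels = labels)
  minor_type <- setdiff(labels, major_type)
  if (!is.null(cfg$mt_insert_mask)) {
    masked <- rep(FALSE, nrow(loci))
    for (i in seq_len(nrow(cfg$mt_insert_mask)))
      masked <- masked | (loci$pos >= cfg$mt_insert_mask[i, 1L] &
                          loci$pos <= cfg$mt_insert_mask[i, 2L])
    loci <- loci[!masked, , drop = FALSE]
  }
  d <- profile$data[match(loci$pos, profile$data$pos), , drop = FALSE]
  usable <- !is.na(d$pos) & d$depth > 0
  if (!any(usable)) stop("zero usable diagnostic loci")
  d <- d[usable, , drop = FALSE]
  loci <- loci[usable, , drop = FALSE]
  minor_allele <- if (major_type == labels[1L]) loci$allele_b else loci$allele_a
  minor_cnt <- counts_at(d, minor_allele)
  freq <- minor_cnt / d$depth
  summary_f <- median(freq)
  supporting <- mean(freq >= cfg$het_cutoff)
  detected <- mean(freq >= cfg$het_cutoff / 2)
  verdict <- if (summary_f >= cfg$het_cutoff &&
                 detected >= cfg$consistency_fraction) "heteroplasmy"
             else "below_cutoff"
  structure(list(sample_id = profile$sample_id, major_type = major_type,
                 minor_type = minor_type,
                 per_locus = data.frame(pos = loci$pos, minor_freq = freq,
                                        depth = d$depth),
                 minor_fraction = summary_f,
                 minor_fraction_mean = mean(freq),
                 fraction_of_loci_supporting = supporting,
                 fraction_of_loci_detected = detected,
                 minor_mean_depth = mean(minor_cnt),
                 nuclear_depth = profile$nuclear_depth,
                 n_usable_loci = nrow(loci),
                 verdict = verdict),
            class = "heteroplasmy_call")
}

#' @export
print.heteroplasmy_call <- function(x, ...) {
  cat(sprintf("heteroplasmy_call '%s': major %s, minor fraction %.4f (median over %d loci), verdict %s\n",
              x$sample_id, x$major_type, x$minor_fraction, x$n_usable_loci,
              x$verdict))
  invisible(x)
}

#' Depth-ratio guard against organellar-insert artifacts
#'
#' A genuine minor plastome type is sequenced at plastid depth, far above
#' the nuclear coverage; a nuclear or mitochondrial insert of plastid DNA
#' is sequenced at that compartment's depth. Calls whose minor-allele mean
#' depth is below `numt_ratio_threshold` times the nuclear depth are
#' downgraded to `ambiguous`. Calls already `below_cutoff` are unchanged.
#'
#' @param call A [estimate_minor_fraction()] result.
#' @param cfg A [heteroplasmy_config()].
#' @return The call with its `verdict` (and `depth_ratio`) updated.
#' @export
numt_guard <- function(call, cfg = heteroplasmy_config()) {
  stopifnot(inherits(call, "heteroplasmy_call"))
  if (is.na(call$nuclear_depth) || call$nuclear_depth <= 0)
    stop("nuclear depth estimate required for the depth-ratio guard")
  call$depth_ratio <- call$minor_mean_depth / call$nuclear_depth
  if (call$verdict == "heteroplasmy" &&
      call$depth_ratio < cfg$numt_ratio_threshold)
    call$verdict <- "ambiguous"
  call
}
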