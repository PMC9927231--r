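## Per-site, per-strand, quality-aware base-count profiles.
##
## On-disk dialect (TSV, one row per site):
##   sample pos ref A_f A_r C_f C_r G_f G_r T_f T_r ins_f ins_r del_f del_r depth
## where *_f/*_r are forward/reverse-strand counts of reads passing the
## Phred filter and depth = sum of the A/C/G/T and del counts (insertions
## do not consume a reference position, so they do not add depth).
##
## In memory, a profile produced by the simulator additionally carries a
## `qual_fail` table of identical shape holding the counts of reads that
## fail the Phred>threshold filter; [filter_basecounts()] removes those.
## The written file stores passing counts only, so a write/read round trip
## reproduces the passing counts exactly.

BC_COUNT_COLS <- c("A_f", "A_r", "C_f", "C_r", "G_f", "G_r", "T_f", "T_r",
                   "ins_f", "ins_r", "del_f", "del_r")
BC_DEPTH_COLS <- setdiff(BC_COUNT_COLS, c("ins_f", "ins_r"))

#' Construct a base-count profile
#'
#' @param sample_id Sample identifier.
#' @param data Data frame with columns `pos`, `ref`, the twelve strand-split
#'   count columns (`A_f` ... `del_r`) and `depth`.
#' @param nuclear_depth Mean genome-wide non-organellar coverage for this
#'   sample, used by the depth-ratio guard ([numt_guard()]).
#' @param qual_fail Optional data frame of identical shape carrying counts
#'   of reads failing the Phred filter (simulator output only).
#' @return An object of class `base_count_profile`.
#' @export
base_count_profile <- function(sample_id, data, nuclear_depth = NA_real_,
                               qual_fail = NULL) {
  need <- c("pos", "ref", BC_COUNT_COLS, "depth")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("base-count data lacks columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[, need]
  if (any(diff(data$pos) <= 0L))
    stop("positions must be strictly increasing (duplicate or unsorted pos)")
  cnt <- as.matrix(data[, BC_COUNT_COLS])
  if (any(cnt < 0)) stop("negative count in base-count profile")
  expect_depth <- rowSums(data[, BC_DEPTH_COLS])
  if (any(data$depth != expect_depth))
    stop("depth column inconsistent with per-base counts at pos ",
         data$pos[which(data$depth != expect_depth)[1L]])
  if (!is.null(qual_fail)) {
    qual_fail <- as.data.frame(qual_fail)[, need]
    stopifnot(identical(qual_fail$pos, data$pos))
  }
  structure(list(sample_id = sample_id, data = data,
                 nuclear_depth = as.numeric(nuclear_depth),
                 qual_fail = qual_fail, filtered = FALSE),
            class = "base_count_profile")
}

#' @export
print.base_count_profile <- function(x, ...) {
  cat(sprintf("base_count_profile '%s': %d sites, mean depth %.0f%s\n",
              x$sample_id, nrow(x$data), mean(x$data$depth),
              if (x$filtered) " (filtered)" else ""))
  invisible(x)
}

#' Read a base-count profile from TSV
#'
#' Validates that positions are strictly increasing, counts are
#' non-negative and the depth column equals the sum of the per-base counts.
#'
#' @param path Path to a base-count TSV (dialect documented in
#'   [base_count_profile()]).
#' @param nuclear_depth Optional nuclear-depth estimate to attach.
#' @return A [base_count_profile()].
#' @export
read_basecounts <- function(path, nuclear_depth = NA_real_) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "pos", "ref", BC_COUNT_COLS, "depth")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("base-count TSV lacks columns: ", paste(miss, collapse = ", "))
  sample_id <- unique(d$sample)
  if (length(sample_id) != 1L)
    stop("base-count TSV must contain exactly one sample; found: ",
         paste(sample_id, collapse = ", "))
  base_count_profile(sample_id, d[, setdiff(need, "sample")],
                     nuclear_depth = nuclear_depth)
}

#' Write a base-count profile to TSV
#'
#' Writes the quality-passing counts only (the on-disk dialect); any
#' attached sub-threshold counts are dropped.
#'
#' @param profile A [base_count_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_basecounts <- function(profile, path) {
  stopifnot(inherits(profile, "base_count_profile"))
  out <- cbind(sample = profile$sample_id, profile$data)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
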