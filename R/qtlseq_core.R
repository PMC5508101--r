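#' SNP-index from allele depths
#'
#' The SNP-index is the fraction of reads at a SNP carrying the allele
#' that differs from the reference parent's assembly:
#' `depth_alt / (depth_ref + depth_alt)`.
#'
#' @param depth_ref,depth_alt Non-negative read counts (vectorized).
#' @return SNP-index in \[0, 1\]; `NA` where total depth is zero.
#' @export
compute_snp_index <- function(depth_ref, depth_alt) {
  tot <- depth_ref + depth_alt
  ifelse(tot > 0, depth_alt / tot, NA_real_)
}

#' Delta(SNP-index) between the two bulks
#'
#' @param index_early,index_late Per-SNP indices of the early and late
#'   bulk, each in \[0, 1\].
#' @param orientation `"early_minus_late"` (default) or
#'   `"late_minus_early"`. With the early parent as the reference
#'   assembly, QTL SNPs fixed in the bulks give delta near -1 under the
#'   default orientation; downstream calling uses |delta| plus the
#'   per-bulk index criteria, so the convention only fixes the sign of
#'   reported values.
#' @return `index_early - index_late` (or its negative), in \[-1, 1\].
#' @export
delta_snp_index <- function(index_early, index_late,
                            orientation = c("early_minus_late",
                                            "late_minus_early")) {
  orientation <- match.arg(orientation)
  d <- index_early - index_late
  if (orientation == "late_minus_early") d <- -d
  d
}

#' Default sample-role map for synthetic tables
#' @return Named list mapping roles to sample names.
#' @export
default_roles <- function() {
  list(parent_early = "parent_early", parent_late = "parent_late",
       bulk_early = "bulk_early", bulk_late = "bulk_late")
}

#' Filter SNPs for QTL-seq analysis
#'
#' Applies the standard QTL-seq filters: total read depth >= `min_depth`
#' in both bulks, mean base quality >= `min_bq`, parents homozygous and
#' differentiated (parental SNP-indices rounding to 0 and 1 at the
#' 0.1/0.9 cut-offs), and removal of SNPs whose index is below
#' `low_index_floor` in both bulks (likely alignment or call artefacts).
#'
#' @param counts An `allele_counts` table.
#' @param roles Role map (see [default_roles()]); `parent_early` /
#'   `parent_late` may be `NULL` to skip the parental filter.
#' @param min_depth Minimum total depth per bulk.
#' @param min_bq Minimum mean base quality (rows with `NA` quality pass).
#' @param low_index_floor Floor for the both-bulks low-index filter; set
#'   to `0` (or `NULL`) to disable.
#' @return Filtered `allele_counts` table; per-filter removal counts in
#'   `attr(, "filter_counts")`.
#' @export
filter_snps <- function(counts, roles = default_roles(), min_depth = 10,
                        min_bq = 20, low_index_floor = 0.3) {
  idx <- function(sample) {
    compute_snp_index(counts[[paste0(sample, "_ref")]],
                      counts[[paste0(sample, "_alt")]])
  }
  depth <- function(sample) {
    counts[[paste0(sample, "_ref")]] + counts[[paste0(sample, "_alt")]]
  }
  keep <- rep(TRUE, nrow(counts))
  removed <- c(depth = 0L, base_quality = 0L, parental = 0L, low_index = 0L)
  ok <- depth(roles$bulk_early) >= min_depth & depth(roles$bulk_late) >= min_depth
  removed["depth"] <- sum(keep & !ok); keep <- keep & ok
  ok <- is.na(counts$mean_bq) | counts$mean_bq >= min_bq
  removed["base_quality"] <- sum(keep & !ok); keep <- keep & ok
  if (!is.null(roles$parent_early) && !is.null(roles$parent_late)) {
    pe <- idx(roles$parent_early); pl <- idx(roles$parent_late)
    ok <- !is.na(pe) & !is.na(pl) &
      ((pe <= 0.1 & pl >= 0.9) | (pe >= 0.9 & pl <= 0.1))
    removed["parental"] <- sum(keep & !ok); keep <- keep & ok
  }
  if (!is.null(low_index_floor) && low_index_floor > 0) {
    be <- idx(roles$bulk_early); bl <- idx(roles$bulk_late)
    ok <- !(be < low_index_floor & bl < low_index_floor)
    ok[is.na(ok)] <- FALSE
    removed["low_index"] <- sum(keep & !ok); keep <- keep & ok
  }
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warning("no SNPs pass the filters")
  attr(out, "samples") <- attr(counts, "samples")
  attr(out, "filter_counts") <- removed
  class(out) <- class(counts)
  out
}

#' Per-SNP SNP-index records for both bulks
#'
#' @param counts A (filtered) `allele_counts` table.
#' @param roles Role map naming `bulk_early` and `bulk_late` samples.
#' @param orientation Passed to [delta_snp_index()].
#' @return Data frame with `chrom`, `pos`, `index_early`, `index_late`,
#'   `delta`, `depth_early`, `depth_late`; zero-depth SNPs are dropped.
#' @export
snp_index_records <- function(counts, roles = default_roles(),
                              orientation = "early_minus_late") {
  de <- counts[[paste0(roles$bulk_early, "_ref")]] +
    counts[[paste0(roles$bulk_early, "_alt")]]
  dl <- counts[[paste0(roles$bulk_late, "_ref")]] +
    counts[[paste0(roles$bulk_late, "_alt")]]
  ie <- compute_snp_index(counts[[paste0(roles$bulk_early, "_ref")]],
                          counts[[paste0(roles$bulk_early, "_alt")]])
  il <- compute_snp_index(counts[[paste0(roles$bulk_late, "_ref")]],
                          counts[[paste0(roles$bulk_late, "_alt")]])
  out <- data.frame(chrom = counts$chrom, pos = counts$pos,
                    index_early = ie, index_late = il,
                    delta = delta_snp_index(ie, il, orientation),
                    depth_early = de, depth_late = dl,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$index_early) & !is.na(out$index_late), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# window mean of `value` over SNPs sorted by pos, for windows [starts, ends]
window_means <- function(pos, value, starts, ends) {
  cs <- c(0, cumsum(value))
  lo <- findInterval(starts - 1L, pos)   # SNPs strictly before window
  hi <- findInterval(ends, pos)          # SNPs up to window end
  n <- hi - lo
  mean <- ifelse(n > 0, (cs[hi + 1L] - cs[lo + 1L]) / n, NA_real_)
  list(n = n, mean = mean)
}

#' Sliding-window profile of SNP-index and delta(SNP-index)
#'
#' Windows of width `W` are anchored at position 1 and advanced by `s`;
#' each window's value is the unweighted mean over SNPs it contains.
#' A final partial window (truncated at the chromosome end) is retained
#' when it contains at least one SNP and flagged `partial`. Windows with
#' no SNPs carry `n_snps = 0` and `NA` means and are excluded from QTL
#' calling.
#'
#' @param records SNP-index records from [snp_index_records()] (a single
#'   chromosome; use [lapply()] over chromosomes otherwise).
#' @param W Window size (bp).
#' @param s Step / increment (bp).
#' @param chrom_length Chromosome length (bp).
#' @return A `window_profile` data frame: `chrom`, `window_start`,
#'   `window_end`, `n_snps`, `mean_index_early`, `mean_index_late`,
#'   `mean_delta`, `partial`; `W`, `s`, `chrom_length` kept as attributes.
#' @export
sliding_window_profile <- function(records, W, s, chrom_length) {
  if (W <= 0 || s <= 0) stop("W and s must be positive")
  if (length(unique(records$chrom)) > 1)
    stop("records span multiple chromosomes; profile one at a time")
  if (W > chrom_length) {
    warning("window size exceeds chromosome length; single clamped window")
    W <- chrom_length
  }
  o <- order(records$pos)
  records <- records[o, , drop = FALSE]
  starts <- seq(1, chrom_length - W + 1, by = s)
  ends <- starts + W - 1
  partial <- rep(FALSE, length(starts))
  last <- starts[length(starts)]
  if (last + W - 1 < chrom_length && last + s <= chrom_length) {
    starts <- c(starts, last + s)
    ends <- c(ends, chrom_length)
    partial <- c(partial, TRUE)
  }
  me <- window_means(records$pos, records$index_early, starts, ends)
  ml <- window_means(records$pos, records$index_late, starts, ends)
  md <- window_means(records$pos, records$delta, starts, ends)
  out <- data.frame(chrom = if (nrow(records)) records$chrom[1] else NA_character_,
                    window_start = starts, window_end = ends,
                    n_snps = me$n,
                    mean_index_early = me$mean, mean_index_late = ml$mean,
                    mean_delta = md$mean, partial = partial,
                    stringsAsFactors = FALSE)
  keep <- !out$partial | out$n_snps > 0
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "W") <- W
  attr(out, "s") <- s
  attr(out, "chrom_length") <- chrom_length
  class(out) <- c("window_profile", "data.frame")
  out
}
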