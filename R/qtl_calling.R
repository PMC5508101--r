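#' Call QTL intervals from a banded window profile
#'
#' A window is significant when it contains SNPs, |mean delta| exceeds the
#' null band at the requested confidence level, |mean delta| > `min_delta`,
#' the higher-index bulk mean is >= `early_min` and the lower-index bulk
#' mean is <= `late_max`. Maximal runs of at least `min_windows`
#' consecutive significant windows of a common delta sign become
#' intervals, with endpoints snapped to the outermost SNPs inside the run.
#'
#' @param profile Banded `window_profile` (see [attach_bands()]).
#' @param records SNP-index records the profile was computed from.
#' @param level Confidence level: 95, 99 or 99.9.
#' @param min_delta Minimum |mean delta| per window.
#' @param early_min Minimum mean SNP-index required of the high-index bulk.
#' @param late_max Maximum mean SNP-index allowed for the low-index bulk.
#' @param min_windows Minimum run length in windows.
#' @param population Population label recorded on each call.
#' @return A data frame of QTL intervals: `chrom`, `start_snp_pos`,
#'   `end_snp_pos`, `length_bp`, `peak_delta` (signed, max |delta| SNP),
#'   `mean_index_early`, `mean_index_late`, `n_windows`, `population`,
#'   `level`.
#' @export
call_qtls <- function(profile, records, level = 99.9, min_delta = 0.5,
                      early_min = 0.8, late_max = 0.2, min_windows = 2L,
                      population = "pop") {
  key <- c("95" = "95", "99" = "99", "99.9" = "999")[as.character(level)]
  if (is.na(key)) stop("level must be 95, 99 or 99.9")
  lo_col <- paste0("ci", key, "_low"); hi_col <- paste0("ci", key, "_high")
  if (!hi_col %in% names(profile)) stop("bands not attached to profile")
  empty <- data.frame(chrom = character(), start_snp_pos = integer(),
                      end_snp_pos = integer(), length_bp = integer(),
                      peak_delta = numeric(), mean_index_early = numeric(),
                      mean_index_late = numeric(), n_windows = integer(),
                      population = character(), level = numeric(),
                      stringsAsFactors = FALSE)
  nonempty <- profile$n_snps > 0
  if (!any(nonempty)) {
    warning("no windows contain SNPs")
    return(empty)
  }
  md <- profile$mean_delta
  hi_bulk <- pmax(profile$mean_index_early, profile$mean_index_late)
  lo_bulk <- pmin(profile$mean_index_early, profile$mean_index_late)
  sig <- nonempty &
    (md > profile[[hi_col]] | md < profile[[lo_col]]) &
    abs(md) > min_delta & hi_bulk >= early_min & lo_bulk <= late_max
  sig[is.na(sig)] <- FALSE
  if (!any(sig)) return(empty)
  # split candidate windows into runs of consecutive indices and same sign
  run_id <- cumsum(c(TRUE, diff(which(sig)) != 1 |
                       diff(sign(md[sig])) != 0))
  calls <- list()
  for (rid in unique(run_id)) {
    w <- which(sig)[run_id == rid]
    if (length(w) < min_windows) next
    span_lo <- min(profile$window_start[w])
    span_hi <- max(profile$window_end[w])
    in_span <- records$pos >= span_lo & records$pos <= span_hi
    if (!any(in_span)) next
    snps <- records[in_span, , drop = FALSE]
    pk <- snps$delta[which.max(abs(snps$delta))]
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = profile$chrom[w[1]],
      start_snp_pos = min(snps$pos), end_snp_pos = max(snps$pos),
      length_bp = max(snps$pos) - min(snps$pos),
      peak_delta = pk,
      mean_index_early = mean(snps$index_early),
      mean_index_late = mean(snps$index_late),
      n_windows = length(w), population = population, level = level,
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out[order(out$chrom, out$start_snp_pos), , drop = FALSE]
}

#' Length of a QTL interval between flanking SNPs
#'
#' Reported as the coordinate difference `end - start` (the convention
#' that reproduces printed interval sizes from printed flanking SNP
#' positions), in bp, kb (one decimal) or Mb (two decimals).
#'
#' @param start_pos,end_pos Flanking SNP positions (1-based bp).
#' @param unit `"bp"`, `"kb"` or `"Mb"`.
#' @return Rounded length in the requested unit.
#' @export
interval_length <- function(start_pos, end_pos, unit = c("bp", "kb", "Mb")) {
  unit <- match.arg(unit)
  if (any(start_pos >= end_pos)) stop("start must be < end")
  bp <- end_pos - start_pos
  switch(unit, bp = bp, kb = round(bp / 1e3, 1), Mb = round(bp / 1e6, 2))
}

#' Intersect QTL calls from two populations sharing a parent
#'
#' The multiple QTL-seq narrowing step: each pair of overlapping intervals
#' on the same chromosome with the same delta sign yields a consensus
#' interval `[max(starts), min(ends)]`; calls with no overlapping partner
#' are reported as population-specific.
#'
#' @param calls_a,calls_b QTL interval data frames from [call_qtls()].
#' @return List with `consensus` (data frame: `chrom`, `start`, `end`,
#'   `length_bp`, `source_a`, `source_b` interval IDs) and `specific`
#'   (unmatched intervals with their population labels), both sorted by
#'   `(chrom, start)`.
#' @export
intersect_qtls <- function(calls_a, calls_b) {
  id_of <- function(x, tag) paste0(tag, seq_len(nrow(x)))
  ia <- id_of(calls_a, "A"); ib <- id_of(calls_b, "B")
  cons <- list()
  used_a <- logical(nrow(calls_a)); used_b <- logical(nrow(calls_b))
  for (i in seq_len(nrow(calls_a))) {
    for (j in seq_len(nrow(calls_b))) {
      if (calls_a$chrom[i] != calls_b$chrom[j]) next
      if (sign(calls_a$peak_delta[i]) != sign(calls_b$peak_delta[j])) next
      s <- max(calls_a$start_snp_pos[i], calls_b$start_snp_pos[j])
      e <- min(calls_a$end_snp_pos[i], calls_b$end_snp_pos[j])
      if (s >= e) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      cons[[length(cons) + 1L]] <- data.frame(
        chrom = calls_a$chrom[i], start = s, end = e, length_bp = e - s,
        source_a = ia[i], source_b = ib[j], stringsAsFactors = FALSE)
    }
  }
  consensus <- if (length(cons)) do.call(rbind, cons) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               length_bp = integer(), source_a = character(),
               source_b = character(), stringsAsFactors = FALSE)
  consensus <- consensus[order(consensus$chrom, consensus$start), , drop = FALSE]
  rownames(consensus) <- NULL
  spec <- rbind(
    if (any(!used_a)) cbind(calls_a[!used_a, , drop = FALSE], interval_id = ia[!used_a]),
    if (any(!used_b)) cbind(calls_b[!used_b, , drop = FALSE], interval_id = ib[!used_b]))
  if (is.null(spec))
    spec <- cbind(calls_a[0, , drop = FALSE], interval_id = character())
  spec <- spec[order(spec$chrom, spec$start_snp_pos), , drop = FALSE]
  rownames(spec) <- NULL
  list(consensus = consensus, specific = spec)
}

#' Delineate candidate SNPs and genes inside a consensus interval
#'
#' Candidate SNPs are those whose |delta| is within `top_delta_tol` of the
#' interval maximum; each is mapped to its containing or flanking gene via
#' [classify_location()]. Genes are ranked by their count of maximal-delta
#' SNPs, ties broken by proximity to the position of the peak-|delta| SNP.
#'
#' @param chrom,start,end Consensus interval (1-based inclusive bp).
#' @param records SNP-index records.
#' @param gene_models Named list of `gene_model` objects.
#' @param top_delta_tol Tolerance below the interval's maximum |delta|.
#' @param urr_len,drr_len Regulatory-window lengths passed to
#'   [classify_location()].
#' @return List with `snps` (data frame: `pos`, `delta`, `category`,
#'   `gene_id`) and `genes` (data frame: `gene_id`, `n_snps`,
#'   `dist_to_peak`, ranked).
#' @export
delineate_candidates <- function(chrom, start, end, records, gene_models,
                                 top_delta_tol = 0, urr_len = 2000,
                                 drr_len = 2000) {
  snps <- records[records$chrom == chrom & records$pos >= start &
                    records$pos <= end, , drop = FALSE]
  if (!nrow(snps)) stop("consensus interval contains no SNPs")
  maxd <- max(abs(snps$delta))
  cand <- snps[abs(snps$delta) >= maxd - top_delta_tol, , drop = FALSE]
  peak_pos <- snps$pos[which.max(abs(snps$delta))]
  cls <- classify_location(cand$pos, gene_models, urr_len = urr_len,
                           drr_len = drr_len)
  snp_out <- data.frame(pos = cand$pos, delta = cand$delta,
                        category = cls$category, gene_id = cls$gene_id,
                        stringsAsFactors = FALSE)
  hit <- snp_out[!is.na(snp_out$gene_id), , drop = FALSE]
  if (nrow(hit)) {
    tab <- table(hit$gene_id)
    dist <- vapply(names(tab), function(g) {
      gm <- gene_models[[g]]
      mid <- (gm$start + gm$end) / 2
      abs(mid - peak_pos)
    }, numeric(1))
    genes <- data.frame(gene_id = names(tab), n_snps = as.integer(tab),
                        dist_to_peak = dist, stringsAsFactors = FALSE)
    genes <- genes[order(-genes$n_snps, genes$dist_to_peak, genes$gene_id), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(gene_id = character(), n_snps = integer(),
                        dist_to_peak = numeric(), stringsAsFactors = FALSE)
  }
  list(snps = snp_out, genes = genes, peak_pos = peak_pos)
}
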