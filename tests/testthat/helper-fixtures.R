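# Shared fixtures, built in code at test time.

# small allele-count data frame builder; depths given as list(sample = cbind(ref, alt))
make_counts <- function(pos, depths, chrom = "chr4", ref = "A", alt = "G",
                        mean_bq = 36) {
  df <- data.frame(chrom = chrom, pos = pos,
                   ref = rep_len(ref, length(pos)),
                   alt = rep_len(alt, length(pos)),
                   mean_bq = rep_len(mean_bq, length(pos)),
                   stringsAsFactors = FALSE)
  for (s in names(depths)) {
    df[[paste0(s, "_ref")]] <- depths[[s]][, 1]
    df[[paste0(s, "_alt")]] <- depths[[s]][, 2]
  }
  allele_counts(df)
}

# ideal four-sample table: parents fixed 0/1, bulks at given indices, depth 30
make_bulk_counts <- function(pos, idx_early, idx_late, depth = 30, ...) {
  n <- length(pos)
  d <- function(p) cbind(round(depth * (1 - p)), round(depth * p))
  make_counts(pos, list(parent_early = d(rep(0, n)), parent_late = d(rep(1, n)),
                        bulk_early = d(rep_len(idx_early, n)),
                        bulk_late = d(rep_len(idx_late, n))), ...)
}

# null bands shared across test files (cached; ~1 s to build)
shared_bands <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- null_bands(10, 9, depths = c(10, 20, 30, 50, 75),
                           n_reps = 10000, seed = 424)
    cache
  }
})

# end-to-end synthetic QTL-seq run on one population; returns records+profile
run_synthetic_pop <- function(seed, qtls, n_ril = 80, chrom_length = 25e6,
                              marker_spacing = 10000, W = 2e6, s = 2.5e5,
                              h2 = 0.9, bands = shared_bands()) {
  cfg <- sim_config(n_ril = n_ril, chrom_lengths = c(chr4 = chrom_length),
                    marker_spacing = marker_spacing, qtls = qtls, h2 = h2,
                    bulk_size = 10)
  truth <- simulate_ril_population(cfg, seed = seed)
  ph <- simulate_phenotypes(truth, cfg, seed = seed + 100)
  bulks <- constitute_bulks(truth, ph)
  counts <- simulate_bulk_readcounts(truth, bulks, cfg, seed = seed + 200)
  rec <- snp_index_records(suppressWarnings(filter_snps(counts)))
  prof <- sliding_window_profile(rec, W = W, s = s, chrom_length = chrom_length)
  prof <- attach_bands(prof, rec, bands)
  list(truth = truth, pheno = ph, bulks = bulks, counts = counts,
       records = rec, profile = prof, config = cfg)
}

no_qtl <- data.frame(chrom = character(), pos = numeric(), effect = numeric())

# brute-force pi: mean Hamming distance over all haplotype pairs
brute_pi <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2)
}

# interval with strongest window support, for recovery checks
main_interval <- function(calls) {
  calls[order(-calls$n_windows, -abs(calls$peak_delta)), , drop = FALSE][1, ]
}
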