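#' Simulate the null distribution of delta(SNP-index)
#'
#' Each replicate draws, independently for each bulk, `bulk_size`
#' individual genotypes from the null RIL genotype distribution at the
#' given selfing generation (residual heterozygote frequency
#' h = (1/2)^(generation-1); the two homozygote classes each at
#' (1-h)/2), computes the bulk allele frequency as mean dosage / 2,
#' samples reads Binomial(depth, frequency) per bulk, and records
#' delta = index_early - index_late.
#'
#' @param bulk_size Individuals per bulk.
#' @param generation Selfing generation (F9 = 9).
#' @param depth Read depth per bulk per SNP.
#' @param n_reps Number of null replicates.
#' @param seed Optional RNG seed.
#' @return Numeric vector of `n_reps` null delta values.
#' @export
simulate_null_delta <- function(bulk_size, generation, depth, n_reps = 10000L,
                                seed = NULL) {
  if (bulk_size < 1 || depth < 1) stop("bulk_size and depth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  h <- (1 / 2)^(generation - 1)
  bulk_freq <- function() {
    n_het <- stats::rbinom(n_reps, bulk_size, h)
    n_hom2 <- stats::rbinom(n_reps, bulk_size - n_het, 0.5)
    (n_het + 2 * n_hom2) / (2 * bulk_size)
  }
  p_e <- bulk_freq()
  p_l <- bulk_freq()
  idx_e <- stats::rbinom(n_reps, depth, p_e) / depth
  idx_l <- stats::rbinom(n_reps, depth, p_l) / depth
  idx_e - idx_l
}

band_levels <- c("95" = 0.95, "99" = 0.99, "999" = 0.999)

#' Null confidence bands for delta(SNP-index) over a depth grid
#'
#' Two-sided empirical quantile bands of the simulated null delta at the
#' 95%, 99% and 99.9% confidence levels, per read depth. Bounds at
#' intermediate depths are obtained by linear interpolation (see
#' [attach_bands()]).
#'
#' @param bulk_size Individuals per bulk.
#' @param generation Selfing generation.
#' @param depths Depth grid to simulate.
#' @param n_reps Replicates per depth.
#' @param seed RNG seed (required for reproducibility).
#' @return A `null_bands` data frame: `depth`, then `p95_low`, `p95_high`,
#'   `p99_low`, `p99_high`, `p999_low`, `p999_high`; simulation settings
#'   kept as attributes.
#' @export
null_bands <- function(bulk_size, generation,
                       depths = c(10, 20, 30, 50, 75, 100, 150),
                       n_reps = 10000L, seed) {
  if (n_reps < 1000) stop("n_reps must be >= 1000")
  set.seed(seed)
  rows <- lapply(sort(depths), function(d) {
    delta <- simulate_null_delta(bulk_size, generation, d, n_reps)
    out <- data.frame(depth = d)
    for (nm in names(band_levels)) {
      a <- (1 - band_levels[[nm]]) / 2
      q <- stats::quantile(delta, c(a, 1 - a), names = FALSE, type = 7)
      out[[paste0("p", nm, "_low")]] <- q[1]
      out[[paste0("p", nm, "_high")]] <- q[2]
    }
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "bulk_size") <- bulk_size
  attr(out, "generation") <- generation
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("null_bands", "data.frame")
  out
}

# interpolate a band column at arbitrary depths (nearest grid value
# outside the grid, with a warning below the simulated minimum)
band_at_depth <- function(bands, column, depth) {
  if (any(depth < min(bands$depth)))
    warning("depth below simulated grid; using nearest grid value")
  stats::approx(bands$depth, bands[[column]], xout = depth, rule = 2)$y
}

#' Attach null confidence bands to a window profile
#'
#' Per SNP, bounds are looked up (with linear interpolation over the depth
#' grid) at that SNP's `min(depth_early, depth_late)`; per window, the
#' bound is the mean of its member SNPs' bounds, mirroring the window mean
#' of delta.
#'
#' @param profile A `window_profile` from [sliding_window_profile()].
#' @param records The SNP-index records the profile was computed from.
#' @param bands A `null_bands` table.
#' @return The profile with added columns `ci95_low`, `ci95_high`,
#'   `ci99_low`, `ci99_high`, `ci999_low`, `ci999_high`.
#' @export
attach_bands <- function(profile, records, bands) {
  o <- order(records$pos)
  records <- records[o, , drop = FALSE]
  d <- pmin(records$depth_early, records$depth_late)
  for (nm in names(band_levels)) {
    for (side in c("low", "high")) {
      per_snp <- band_at_depth(bands, paste0("p", nm, "_", side), d)
      wm <- window_means(records$pos, per_snp,
                         profile$window_start, profile$window_end)
      profile[[paste0("ci", nm, "_", side)]] <- wm$mean
    }
  }
  profile
}
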