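#' Construct a haplotype matrix
#'
#' @param mat Integer matrix, haplotypes x sites, alleles coded 0 (ref)
#'   and 1 (alt).
#' @param positions Site positions (1-based bp), one per column.
#' @param label Panel label (e.g. `"cultivated"`, `"wild"`).
#' @return A `haplotype_matrix` list with fields `mat`, `positions`,
#'   `label`.
#' @export
haplotype_matrix <- function(mat, positions, label = "") {
  if (ncol(mat) != length(positions))
    stop("positions length must match number of sites")
  if (nrow(mat) < 2) stop("need >= 2 haplotypes")
  if (!all(mat %in% c(0L, 1L))) stop("alleles must be 0/1")
  o <- order(positions)
  structure(list(mat = mat[, o, drop = FALSE], positions = positions[o],
                 label = label), class = "haplotype_matrix")
}

#' Expand diploid dosages to haplotypes under inbreeding
#'
#' Selfing-species panels are genotyped as 0/1/2 dosages; homozygotes
#' expand to two identical haplotypes and residual heterozygotes to one
#' reference plus one alternate haplotype.
#'
#' @param dosage Integer matrix, individuals x sites, values 0/1/2.
#' @param positions Site positions.
#' @param label Panel label.
#' @return A `haplotype_matrix` with `2 * nrow(dosage)` haplotypes.
#' @export
dosage_to_haplotypes <- function(dosage, positions, label = "") {
  if (!all(dosage %in% 0:2)) stop("dosages must be 0/1/2")
  h1 <- (dosage >= 1L) * 1L  # carries alt if dosage 1 or 2
  h2 <- (dosage == 2L) * 1L
  haplotype_matrix(rbind(h1, h2), positions, label)
}

#' Nucleotide diversity (theta-pi) per window
#'
#' pi = sum over sites of (n/(n-1)) * 2 * p * (1 - p), the average number
#' of pairwise differences between haplotypes; equal to the mean Hamming
#' distance over all haplotype pairs.
#'
#' @param hap A `haplotype_matrix`.
#' @param window_size Non-overlapping window size in bp (default 100 kb).
#' @param chrom_length Optional total span (defaults to the last site).
#' @return A data frame of windows: `start`, `end`, `n_sites`,
#'   `n_segregating`, `pi_sum`, `pi_per_site`, `theta_w`, `tajima_d`.
#' @export
diversity_windows <- function(hap, window_size = 100000L, chrom_length = NULL) {
  n <- nrow(hap$mat)
  p <- colMeans(hap$mat)
  site_pi <- n / (n - 1) * 2 * p * (1 - p)
  seg <- p > 0 & p < 1
  if (is.null(chrom_length)) chrom_length <- max(hap$positions)
  starts <- seq(1, chrom_length, by = window_size)
  ends <- pmin(starts + window_size - 1, chrom_length)
  bin <- findInterval(hap$positions, starts)
  rows <- lapply(seq_along(starts), function(w) {
    in_w <- bin == w
    S <- sum(seg[in_w])
    pi_sum <- sum(site_pi[in_w])
    data.frame(start = starts[w], end = ends[w],
               n_sites = sum(in_w), n_segregating = S,
               pi_sum = pi_sum,
               pi_per_site = if (sum(in_w) > 0) pi_sum / sum(in_w) else NA_real_,
               theta_w = S / tajima_constants(n)$a1,
               tajima_d = if (n >= 4) tajimas_d(pi_sum, S, n) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tajima's D constants for sample size n
#'
#' The standard coefficients: a1 = sum 1/i, a2 = sum 1/i^2 (i = 1..n-1),
#' b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2).
#'
#' @param n Number of haplotypes (>= 2).
#' @return Named list of the constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("need n >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from window summaries
#'
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1)). Negative D indicates an
#' excess of rare variants (e.g. after a bottleneck or sweep), positive D
#' an excess of intermediate-frequency variants.
#'
#' @param pi_sum Sum of per-site pi over the window.
#' @param S Number of segregating sites.
#' @param n Number of haplotypes (>= 4 for a meaningful test).
#' @return D, or `NA` when `S` is 0 or the variance term vanishes.
#' @export
tajimas_d <- function(pi_sum, S, n) {
  if (S < 1) return(NA_real_)
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) stop("non-positive variance term in Tajima's D")
  (pi_sum - S / k$a1) / sqrt(v)
}

#' Cultivated/wild nucleotide-diversity ratio over a region
#'
#' 100 x (mean per-site pi over the region in the cultivated panel) /
#' (same in the wild panel), the theta-pi(cultivated)/theta-pi(wild)
#' percentage used to quantify domestication-associated diversity loss.
#'
#' @param panel_c,panel_w `haplotype_matrix` objects on identical site
#'   positions.
#' @param region Length-2 vector `c(start, end)` in bp.
#' @return List with `ratio_pct` (one decimal), `pi_c`, `pi_w` (per-site
#'   means over the region).
#' @export
diversity_ratio <- function(panel_c, panel_w, region) {
  if (!identical(panel_c$positions, panel_w$positions))
    stop("panels must share site positions")
  in_r <- panel_c$positions >= region[1] & panel_c$positions <= region[2]
  if (!any(in_r)) stop("no sites inside region")
  per_site <- function(panel) {
    n <- nrow(panel$mat)
    p <- colMeans(panel$mat[, in_r, drop = FALSE])
    mean(n / (n - 1) * 2 * p * (1 - p))
  }
  pi_c <- per_site(panel_c)
  pi_w <- per_site(panel_w)
  if (pi_w == 0) {
    warning("wild-panel diversity is zero in region; ratio undefined")
    return(list(ratio_pct = NA_real_, pi_c = pi_c, pi_w = pi_w))
  }
  list(ratio_pct = round(100 * pi_c / pi_w, 1), pi_c = pi_c, pi_w = pi_w)
}

#' Phenotypic variance explained by a single marker
#'
#' Coefficient of determination of the one-way genotype-class-means model
#' (a deliberately simple single-marker association utility; no kinship or
#' structure correction).
#'
#' @param genotypes Dosage vector (0/1/2) per individual.
#' @param phenotypes Numeric trait values, same length.
#' @return R-squared in percent.
#' @export
single_marker_pve <- function(genotypes, phenotypes) {
  if (length(genotypes) != length(phenotypes)) stop("length mismatch")
  if (length(genotypes) < 3) stop("need >= 3 individuals")
  if (length(unique(genotypes)) < 2) stop("monomorphic marker")
  fit <- stats::lm(phenotypes ~ factor(genotypes))
  100 * summary(fit)$r.squared
}
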