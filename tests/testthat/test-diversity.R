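test_that("theta-pi equals brute-force average pairwise differences", {
  # two haplotypes differing at 3 sites: pi = 3
  m <- rbind(c(0, 0, 0, 1, 1), c(1, 1, 0, 1, 0))
  h <- haplotype_matrix(m, positions = 1:5 * 100)
  w <- diversity_windows(h, window_size = 1000)
  expect_equal(w$pi_sum, 3)
  # monomorphic window: pi = 0
  h0 <- haplotype_matrix(matrix(0L, 4, 3), positions = c(10, 20, 30))
  expect_equal(diversity_windows(h0, window_size = 100)$pi_sum, 0)
  # random 20 x 50 matrices match the oracle to 1e-10
  set.seed(91)
  for (rep in 1:5) {
    m <- matrix(rbinom(20 * 50, 1, runif(1, 0.1, 0.5)), nrow = 20)
    m[1, ] <- 1L - m[2, ]  # guarantee >= 1 segregating site
    h <- haplotype_matrix(m, positions = seq_len(50))
    w <- diversity_windows(h, window_size = 100)
    expect_equal(w$pi_sum, brute_pi(m), tolerance = 1e-10)
  }
})

test_that("pi and D are invariant to sample order and allele relabelling", {
  set.seed(92)
  m <- matrix(rbinom(20 * 40, 1, 0.3), nrow = 20)
  h <- haplotype_matrix(m, positions = seq_len(40))
  w <- diversity_windows(h, window_size = 100)
  h2 <- haplotype_matrix(m[sample.int(20), ], positions = seq_len(40))
  expect_equal(diversity_windows(h2, window_size = 100), w)
  flip <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  m3 <- m
  m3[, flip] <- 1L - m3[, flip]
  h3 <- haplotype_matrix(m3, positions = seq_len(40))
  expect_equal(diversity_windows(h3, window_size = 100), w)
})

test_that("Tajima's constants satisfy the published identities", {
  for (n in 4:50) {
    k <- tajima_constants(n)
    i <- seq_len(n - 1)
    expect_equal(k$a1, sum(1 / i))
    expect_equal(k$c1, k$b1 - 1 / k$a1, tolerance = 1e-12)
    expect_equal(k$c2, k$b2 - (n + 2) / (k$a1 * n) + k$a2 / k$a1^2,
                 tolerance = 1e-12)
    expect_equal(k$e1, k$c1 / k$a1, tolerance = 1e-12)
    expect_equal(k$e2, k$c2 / (k$a1^2 + k$a2), tolerance = 1e-12)
  }
})

test_that("Tajima's D matches an independent constant-by-constant oracle", {
  # 4 haplotypes {0000, 0000, 1111, 1111}, S = 4
  m <- rbind(rep(0L, 4), rep(0L, 4), rep(1L, 4), rep(1L, 4))
  h <- haplotype_matrix(m, positions = 1:4)
  w <- diversity_windows(h, window_size = 10)
  n <- 4; S <- 4
  # oracle computed from first principles in this test
  pi <- brute_pi(m)
  a1 <- 1 + 1 / 2 + 1 / 3
  a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  d_oracle <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(w$tajima_d, d_oracle, tolerance = 1e-10)
  expect_equal(w$n_segregating, 4L)
  # all-singleton configuration: excess rare variants, D < 0
  m2 <- matrix(0L, 10, 5)
  for (j in 1:5) m2[j, j] <- 1L
  h2 <- haplotype_matrix(m2, positions = 1:5)
  expect_lt(diversity_windows(h2, window_size = 10)$tajima_d, 0)
})

test_that("windowed segregating sites are additive over tiles", {
  set.seed(93)
  m <- matrix(rbinom(12 * 200, 1, 0.2), nrow = 12)
  h <- haplotype_matrix(m, positions = sort(sample.int(5000, 200)))
  w <- diversity_windows(h, window_size = 500, chrom_length = 5000)
  p <- colMeans(h$mat)
  expect_equal(sum(w$n_segregating), sum(p > 0 & p < 1))
  expect_equal(sum(w$n_sites), 200L)
})

test_that("neutral wild panels give Tajima's D near zero", {
  ds <- vapply(1:20, function(s) {
    p <- simulate_diversity_panel(50, 50, 1000, reduction = 0, seed = s)
    mean(diversity_windows(p$wild)$tajima_d, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(ds)), 0.5)
})

test_that("subsampling haplotypes leaves the diversity ratio near 100%", {
  # pi is an unbiased estimator: a random half of the wild panel estimates
  # the same per-site diversity
  set.seed(94)
  ratios <- vapply(1:10, function(s) {
    p <- simulate_diversity_panel(50, 50, 1500, reduction = 0, seed = s + 40)
    sub <- haplotype_matrix(p$wild$mat[sample.int(50, 25), ],
                            p$wild$positions, "sub")
    diversity_ratio(sub, p$wild, c(1, 2e6))$ratio_pct
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 100), 3)
})

test_that("a planted 90% sweep reduction is recovered from the ratio", {
  ratios <- vapply(1:20, function(s) {
    p <- simulate_diversity_panel(50, 50, 2000, reduction = 0.9,
                                  sweep_region = c(2e5, 6e5), seed = s)
    diversity_ratio(p$cultivated, p$wild, c(2e5, 6e5))$ratio_pct
  }, numeric(1))
  expect_true(all(ratios >= 5 & ratios <= 15))
  # reduction 0: inside ratio tracks the outside (bottleneck-only) ratio
  p0 <- simulate_diversity_panel(50, 50, 2000, reduction = 0,
                                 sweep_region = c(2e5, 6e5), seed = 99)
  rin <- diversity_ratio(p0$cultivated, p0$wild, c(2e5, 6e5))$ratio_pct
  rout <- diversity_ratio(p0$cultivated, p0$wild, c(6.1e5, 1e6))$ratio_pct
  expect_lt(abs(rin - rout), 15)
})

test_that("dosage matrices expand to haplotypes under inbreeding", {
  dos <- rbind(c(0L, 2L, 1L), c(2L, 2L, 0L))
  h <- dosage_to_haplotypes(dos, positions = c(10, 20, 30))
  expect_equal(nrow(h$mat), 4)
  expect_equal(colSums(h$mat), c(2, 4, 1))
  expect_error(dosage_to_haplotypes(matrix(3L, 2, 1), 1), "0/1/2")
})

test_that("single-marker PVE behaves at the determinism and null extremes", {
  g <- rep(c(0, 1, 2), each = 20)
  # phenotype exactly determined by genotype
  expect_equal(single_marker_pve(g, c(10, 20, 30)[g + 1]), 100)
  expect_error(single_marker_pve(rep(1, 10), rnorm(10)), "monomorphic")
  # independent phenotype: R2 stays small
  set.seed(95)
  null_pve <- vapply(1:20, function(s) {
    single_marker_pve(sample(0:2, 200, replace = TRUE), rnorm(200))
  }, numeric(1))
  expect_gte(sum(null_pve < 5), 18)
  # planted marker explaining ~40% of variance is recovered
  pves <- vapply(1:10, function(s) {
    set.seed(s + 300)
    g <- sample(c(0, 2), 200, replace = TRUE)
    gv <- (g - 1) * 2               # var = 4 at allele freq 1/2
    y <- gv + rnorm(200, 0, sqrt(6)) # PVE = 4/10 = 40%
    single_marker_pve(g, y)
  }, numeric(1))
  expect_lt(abs(mean(pves) - 40), 8)
})
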