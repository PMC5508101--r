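test_that("zero recombination yields whole-chromosome parental blocks", {
  cfg <- sim_config(n_ril = 30, chrom_lengths = c(c1 = 5e6),
                    marker_spacing = 5e5, qtls = no_qtl, recomb_rate = 0)
  truth <- simulate_ril_population(cfg, seed = 1)
  per_ind <- apply(truth$genotypes, 1, function(g) length(unique(g)))
  expect_true(all(per_ind == 1))
})

test_that("F9 heterozygote fraction matches the selfing series (1/2)^8", {
  # one marker on each of ten chromosomes: locus outcomes are independent,
  # so the plain binomial standard error applies
  lens <- stats::setNames(rep(1e6, 10), paste0("c", 1:10))
  cfg <- sim_config(n_ril = 2000, chrom_lengths = lens,
                    marker_spacing = 1e6, qtls = no_qtl)
  truth <- simulate_ril_population(cfg, seed = 2)
  expected <- (1 / 2)^8
  obs <- mean(truth$genotypes == 1L)
  se <- sqrt(expected * (1 - expected) / length(truth$genotypes))
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("recombinant fraction between linked markers follows the RIL map expansion", {
  # markers 1 Mb apart at 1 cM/Mb; Haldane r = 0.5(1 - exp(-0.02)),
  # fully-inbred RIL expectation R = 2r/(1 + 2r)
  cfg <- sim_config(n_ril = 4000, chrom_lengths = c(c1 = 2e6),
                    marker_spacing = 1e6, qtls = no_qtl, recomb_rate = 1)
  truth <- simulate_ril_population(cfg, seed = 99)
  g <- truth$genotypes
  hom <- g[, 1] != 1L & g[, 2] != 1L
  obs <- mean(g[hom, 1] != g[hom, 2])
  r <- 0.5 * (1 - exp(-2 * 0.01))
  r_ril <- 2 * r / (1 + 2 * r)
  se <- sqrt(r_ril * (1 - r_ril) / sum(hom))
  expect_lt(abs(obs - r_ril), 4 * se)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_ril = 20, chrom_lengths = c(c1 = 2e6),
                    marker_spacing = 1e5, qtls = no_qtl)
  t1 <- simulate_ril_population(cfg, seed = 5)
  t2 <- simulate_ril_population(cfg, seed = 5)
  expect_identical(t1$genotypes, t2$genotypes)
  p1 <- simulate_phenotypes(t1, cfg, seed = 6)
  p2 <- simulate_phenotypes(t2, cfg, seed = 6)
  expect_identical(p1, p2)
  b <- constitute_bulks(t1, p1, bulk_size = 5)
  c1 <- simulate_bulk_readcounts(t1, b, cfg, seed = 7)
  c2 <- simulate_bulk_readcounts(t1, b, cfg, seed = 7)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("phenotype construction places parents and scales heritability", {
  cfg <- sim_config(n_ril = 200, chrom_lengths = c(c1 = 10e6),
                    marker_spacing = 1e5,
                    qtls = data.frame(chrom = "c1", pos = c(2e6, 8e6),
                                      effect = c(5, 7)))
  truth <- simulate_ril_population(cfg, seed = 8)
  ph <- simulate_phenotypes(truth, cfg, seed = 9)
  pe <- mean(ph$dtf[ph$role == "parent_early"])
  pl <- mean(ph$dtf[ph$role == "parent_late"])
  # parental means differ by twice the summed additive effects (dosage 0 vs 2)
  expect_lt(abs((pl - pe) - 2 * 12), 5)
  h2 <- broad_sense_heritability(ph)
  expect_lt(abs(h2$h2_percent - 80), 10)
})

test_that("bulk constitution selects disjoint homozygous extremes with ID tie-break", {
  cfg <- sim_config(n_ril = 60, chrom_lengths = c(c1 = 5e6),
                    marker_spacing = 1e5,
                    qtls = data.frame(chrom = "c1", pos = 2.5e6, effect = 10),
                    bulk_size = 10)
  truth <- simulate_ril_population(cfg, seed = 10)
  ph <- simulate_phenotypes(truth, cfg, seed = 11)
  b <- constitute_bulks(truth, ph)
  expect_length(b$early, 10)
  expect_length(b$late, 10)
  expect_length(intersect(b$early, b$late), 0)
  # fully tied phenotypes: deterministic lowest-10 / highest-10 IDs
  ph_tied <- ph
  ph_tied$dtf <- 50
  b2 <- constitute_bulks(truth, ph_tied)
  hom_ids <- rownames(truth$genotypes)[
    apply(truth$genotypes[, abs(truth$markers$pos - 2.5e6) <= 1e6,
                          drop = FALSE] != 1L, 1, all)]
  expect_equal(b2$early, sort(hom_ids)[1:10])
  expect_equal(b2$late, sort(rev(sort(hom_ids))[1:10]))
  expect_error(constitute_bulks(truth, ph, bulk_size = 100),
               "insufficient homozygous")
})

test_that("a large-effect planted QTL fixes the early bulk for the early allele", {
  fixed <- vapply(1:100, function(s) {
    cfg <- sim_config(n_ril = 60, chrom_lengths = c(c1 = 10e6),
                      marker_spacing = 2.5e5,
                      qtls = data.frame(chrom = "c1", pos = 5e6, effect = 15),
                      h2 = 0.9, bulk_size = 10)
    truth <- simulate_ril_population(cfg, seed = s)
    ph <- simulate_phenotypes(truth, cfg, seed = s + 1000)
    b <- constitute_bulks(truth, ph)
    qm <- which.min(abs(truth$markers$pos - 5e6))
    all(truth$genotypes[b$early, qm] == 0L)
  }, logical(1))
  expect_gte(sum(fixed), 95)
})

test_that("read sampling reproduces bulk allele frequencies", {
  cfg <- sim_config(n_ril = 20, chrom_lengths = c(c1 = 10e6),
                    marker_spacing = 1000, qtls = no_qtl, depth_mean = 30)
  markers <- data.frame(chrom = "c1", pos = seq(1000, 10e6, by = 1000))
  # hand-built truth: every individual heterozygous -> p = 0.5 everywhere
  geno <- matrix(1L, nrow = 20, ncol = nrow(markers))
  rownames(geno) <- sprintf("RIL%04d", 1:20)
  truth <- list(genotypes = geno, markers = markers, qtls = no_qtl,
                config = cfg)
  b <- list(early = rownames(geno)[1:10], late = rownames(geno)[11:20])
  cnt <- simulate_bulk_readcounts(truth, b, cfg, seed = 12)
  idx <- compute_snp_index(cnt$bulk_early_ref, cnt$bulk_early_alt)
  expect_lt(abs(mean(idx, na.rm = TRUE) - 0.5), 0.01)
  # bulk fixed for reference -> no alt reads at all
  geno0 <- geno; geno0[] <- 0L
  truth0 <- truth; truth0$genotypes <- geno0
  cnt0 <- simulate_bulk_readcounts(truth0, b, cfg, seed = 13)
  expect_true(all(cnt0$bulk_early_alt == 0L))
  expect_true(all(cnt0$bulk_late_alt == 0L))
})

test_that("generated gene models translate cleanly and validate as GFF3", {
  gm <- generate_gene_models(chrom_length = 60000L, n_genes = 6L, seed = 31)
  for (g in gm$genes) {
    expect_equal(cds_length(g) %% 3L, 0L)
    cds <- mqtlseq:::spliced_cds(g, gm$sequence)
    aa <- as.character(Biostrings::translate(cds))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_equal(substr(aa, 1, 1), "M")
  }
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(gm$genes, path)
  expect_silent(back <- read_gene_models(path))
  expect_length(back, 6)
})
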