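test_that("interval lengths reproduce printed sizes from flanking positions", {
  expect_equal(interval_length(46023168, 46780835, "kb"), 757.7)
  expect_equal(interval_length(26500027, 27407090, "kb"), 907.1)
  expect_equal(interval_length(26100745, 28089632, "Mb"), 1.99)
  expect_equal(interval_length(45600294, 46991993, "Mb"), 1.39)
  expect_equal(interval_length(100, 600, "bp"), 500)
  expect_error(interval_length(10, 10), "start must be < end")
})

test_that("intersecting overlapping calls returns the shared core interval", {
  mk <- function(s, e, pk = -0.9) data.frame(
    chrom = "chr4", start_snp_pos = s, end_snp_pos = e, length_bp = e - s,
    peak_delta = pk, mean_index_early = 0.05, mean_index_late = 0.95,
    n_windows = 5L, population = "p", level = 99.9, stringsAsFactors = FALSE)
  a <- rbind(mk(26100745, 28089632), mk(46023168, 46780835))
  b <- rbind(mk(26500027, 27407090), mk(45600294, 46991993))
  xs <- intersect_qtls(a, b)
  expect_equal(nrow(xs$consensus), 2)
  expect_equal(xs$consensus$start, c(26500027, 46023168))
  expect_equal(xs$consensus$end, c(27407090, 46780835))
  expect_equal(interval_length(xs$consensus$start[1], xs$consensus$end[1], "kb"),
               907.1)
  expect_equal(interval_length(xs$consensus$start[2], xs$consensus$end[2], "kb"),
               757.7)
  # consensus is contained in every source and no longer than the shorter
  expect_true(all(xs$consensus$length_bp <=
                    pmin(a$length_bp, b$length_bp)))
  # commutative up to source labels
  yx <- intersect_qtls(b, a)
  expect_equal(xs$consensus[c("chrom", "start", "end", "length_bp")],
               yx$consensus[c("chrom", "start", "end", "length_bp")])
  # disjoint calls become population-specific records
  xs2 <- intersect_qtls(mk(1e6, 2e6), mk(5e6, 6e6))
  expect_equal(nrow(xs2$consensus), 0)
  expect_equal(nrow(xs2$specific), 2)
  # opposite delta signs never merge
  xs3 <- intersect_qtls(mk(1e6, 2e6, pk = 0.9), mk(1.5e6, 2.5e6, pk = -0.9))
  expect_equal(nrow(xs3$consensus), 0)
})

test_that("degenerate thresholds call one interval spanning all SNPs", {
  pos <- seq(10000, 490000, by = 10000)
  rec <- data.frame(chrom = "c", pos = pos, index_early = 0.05,
                    index_late = 0.95, delta = -0.9,
                    depth_early = 30L, depth_late = 30L)
  prof <- sliding_window_profile(rec, W = 50000, s = 50000,
                                 chrom_length = 5e5)
  prof <- attach_bands(prof, rec, shared_bands())
  cl <- call_qtls(prof, rec, level = 99.9, min_delta = 0,
                  early_min = 0, late_max = 1, min_windows = 1)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start_snp_pos, min(pos))
  expect_equal(cl$end_snp_pos, max(pos))
  expect_equal(cl$peak_delta, -0.9)
  expect_equal(cl$length_bp, max(pos) - min(pos))
})

test_that("every called window satisfies the predicate and runs respect min_windows", {
  set.seed(71)
  pos <- seq(5000, 995000, by = 5000)
  delta <- rep(0, length(pos))
  block <- pos >= 3e5 & pos <= 5e5
  delta[block] <- -0.95
  spike <- which(pos == 800000)
  delta[spike] <- -0.95  # single-window spike, must be suppressed
  ie <- ifelse(delta < -0.5, 0.045, 0.475)  # low bulk index in the block
  rec <- data.frame(chrom = "c", pos = pos,
                    index_early = ie, index_late = ie - delta, delta = delta,
                    depth_early = 30L, depth_late = 30L)
  prof <- sliding_window_profile(rec, W = 50000, s = 25000,
                                 chrom_length = 1e6)
  prof <- attach_bands(prof, rec, shared_bands())
  cl <- call_qtls(prof, rec, level = 99.9, min_delta = 0.5,
                  early_min = 0.8, late_max = 0.2, min_windows = 2)
  expect_equal(nrow(cl), 1)
  expect_lte(cl$start_snp_pos, 3.1e5)
  expect_gte(cl$end_snp_pos, 4.9e5)
  expect_lt(cl$end_snp_pos, 790000)  # spike not merged
  # exhaustive post-check: windows fully inside the called span satisfy the
  # predicate; windows fully outside all called spans fail at least one rule
  key <- "ci999"
  sig <- with(prof, n_snps > 0 &
                (mean_delta > prof[[paste0(key, "_high")]] |
                   mean_delta < prof[[paste0(key, "_low")]]) &
                abs(mean_delta) > 0.5 &
                pmax(mean_index_early, mean_index_late) >= 0.8 &
                pmin(mean_index_early, mean_index_late) <= 0.2)
  sig[is.na(sig)] <- FALSE
  inside <- prof$window_start >= cl$start_snp_pos &
    prof$window_end <= cl$end_snp_pos & prof$n_snps > 0
  expect_true(all(sig[inside]))
})

test_that("candidate delineation ranks genes by maximal-delta SNP count", {
  genes <- list(
    geneA = gene_model("geneA", "c", "+", 10000, 12000,
                       cds_start = 10000, cds_end = 11999),
    geneB = gene_model("geneB", "c", "+", 30000, 32000,
                       cds_start = 30000, cds_end = 31999))
  rec <- data.frame(chrom = "c",
                    pos = c(10100, 10500, 11000, 30500, 20000, 50000),
                    delta = c(1, 1, 1, 1, 0.6, 0.2),
                    index_early = 0, index_late = 1,
                    depth_early = 30L, depth_late = 30L)
  out <- delineate_candidates("c", 1, 60000, rec, genes)
  expect_equal(out$genes$gene_id[1], "geneA")
  expect_equal(out$genes$n_snps[1], 3L)
  expect_equal(nrow(out$snps), 4)  # only delta == 1 SNPs at tol 0
  # full tolerance returns every SNP in the interval
  all_out <- delineate_candidates("c", 1, 60000, rec, genes,
                                  top_delta_tol = 1)
  expect_equal(nrow(all_out$snps), 6)
  # all-intergenic candidates: SNP list survives, gene list is empty
  rec2 <- rec
  rec2$pos <- c(15000, 16000, 17000, 18000, 20000, 50000)
  out2 <- delineate_candidates("c", 14000, 21000, rec2, genes)
  expect_equal(nrow(out2$genes), 0)
  expect_gt(nrow(out2$snps), 0)
  expect_error(delineate_candidates("c", 1, 5000, rec, genes), "no SNPs")
})
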