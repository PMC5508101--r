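#' Default pipeline run configuration
#'
#' Thresholds carry the method's standard values: depth >= 10, mean base
#' quality >= 20, |delta(SNP-index)| > 0.5 with the 99.9% null band,
#' bulk SNP-index criteria 0.8/0.2, 2-kb regulatory windows and 100-kb
#' diversity windows. The two simulated populations share the early
#' parent and both segregate for the same planted QTLs, mirroring the
#' multiple QTL-seq design; window size and chromosome scale are set for
#' a desk-scale synthetic chromosome.
#'
#' @param seed RNG seed governing every stochastic stage.
#' @return Nested configuration list consumed by [run_pipeline()].
#' @export
default_run_config <- function(seed = 7L) {
  list(
    seed = as.integer(seed),
    populations = list(
      popA = list(n_ril = 120L),
      popB = list(n_ril = 100L)
    ),
    sim = list(chrom = "chr4", chrom_length = 25e6, marker_spacing = 10000L,
               qtl_pos = c(8e6, 17.5e6), qtl_effect = c(9, 12),
               h2 = 0.8, depth_mean = 30, bulk_size = 10L, recomb_rate = 3),
    filters = list(min_depth = 10, min_bq = 20, low_index_floor = 0.3),
    windows = list(W = 2e6, s = 250e3),
    bands = list(depths = c(10, 20, 30, 50, 75), n_reps = 5000L),
    calling = list(level = 99.9, min_delta = 0.5, early_min = 0.8,
                   late_max = 0.2, min_windows = 2L),
    annotation = list(urr_len = 2000, drr_len = 2000),
    diversity = list(n_cultivated = 50L, n_wild = 50L, n_sites = 2000L,
                     reduction = 0.9, sweep_region = c(2e5, 6e5),
                     window = 100000L)
  )
}

#' Run the full multiple QTL-seq pipeline on synthetic data
#'
#' Orchestrates simulate -> filter -> SNP-index -> null bands -> window
#' profile -> QTL calling per population, intersects the calls across the
#' two populations (consensus narrowing), delineates candidate SNPs/genes
#' against generated gene models, runs the cultivated/wild diversity
#' scan, and writes every stage's table plus a JSON provenance manifest
#' into `out_dir`. Rerunning with an identical config reproduces
#' identical outputs.
#'
#' @param config Configuration list (see [default_run_config()]) or a
#'   path to a YAML file holding one.
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly; per-stage results in
#'   `attr(, "results")`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  sim <- config$sim
  chrom_lengths <- stats::setNames(sim$chrom_length, sim$chrom)
  qtls <- data.frame(chrom = sim$chrom, pos = sim$qtl_pos,
                     effect = sim$qtl_effect)
  bands <- NULL
  calls <- list()
  records <- list()
  pop_names <- names(config$populations)
  for (k in seq_along(pop_names)) {
    pn <- pop_names[k]
    pop <- config$populations[[pn]]
    cfg <- sim_config(n_ril = pop$n_ril, chrom_lengths = chrom_lengths,
                      marker_spacing = sim$marker_spacing, qtls = qtls,
                      h2 = sim$h2, depth_mean = sim$depth_mean,
                      bulk_size = sim$bulk_size, recomb_rate = sim$recomb_rate)
    pop_seed <- config$seed + 1000L * k
    truth <- simulate_ril_population(cfg, seed = pop_seed)
    pheno <- simulate_phenotypes(truth, cfg, seed = pop_seed + 1L)
    bulks <- constitute_bulks(truth, pheno)
    counts <- simulate_bulk_readcounts(truth, bulks, cfg, seed = pop_seed + 2L)
    write_allele_counts(counts, file.path(out_dir, paste0(pn, "_counts.tsv")))
    utils::write.table(pheno, file.path(out_dir, paste0(pn, "_pheno.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages <- c(stages, paste0("simulate:", pn))
    filt <- filter_snps(counts, min_depth = config$filters$min_depth,
                        min_bq = config$filters$min_bq,
                        low_index_floor = config$filters$low_index_floor)
    rec <- snp_index_records(filt)
    utils::write.table(rec, file.path(out_dir, paste0(pn, "_snp_index.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages <- c(stages, paste0("index:", pn))
    if (is.null(bands)) {
      bands <- null_bands(sim$bulk_size, 9L, depths = config$bands$depths,
                          n_reps = config$bands$n_reps,
                          seed = config$seed + 99L)
      utils::write.table(as.data.frame(bands),
                         file.path(out_dir, "null_bands.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stages <- c(stages, "ci")
    }
    prof <- sliding_window_profile(rec, W = config$windows$W,
                                   s = config$windows$s,
                                   chrom_length = sim$chrom_length)
    prof <- attach_bands(prof, rec, bands)
    utils::write.table(as.data.frame(prof),
                       file.path(out_dir, paste0(pn, "_windows.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cl <- call_qtls(prof, rec, level = config$calling$level,
                    min_delta = config$calling$min_delta,
                    early_min = config$calling$early_min,
                    late_max = config$calling$late_max,
                    min_windows = config$calling$min_windows,
                    population = pn)
    write_intervals(cl, file.path(out_dir, paste0(pn, "_qtls.bed")))
    stages <- c(stages, paste0("call:", pn))
    calls[[pn]] <- cl
    records[[pn]] <- rec
  }
  xs <- intersect_qtls(calls[[1]], calls[[2]])
  if (nrow(xs$consensus)) {
    write_intervals(data.frame(chrom = xs$consensus$chrom,
                               start = xs$consensus$start,
                               end = xs$consensus$end,
                               population = "consensus",
                               peak_delta = 0),
                    file.path(out_dir, "consensus.bed"))
  } else {
    write_intervals(xs$consensus[, c("chrom", "start", "end")],
                    file.path(out_dir, "consensus.bed"))
  }
  stages <- c(stages, "intersect")
  gm <- generate_gene_models(chrom = sim$chrom, seed = config$seed + 7L)
  write_gene_models(gm$genes, file.path(out_dir, "genes.gff3"))
  Biostrings::writeXStringSet(gm$sequence, file.path(out_dir, "reference.fa"))
  ann <- NULL
  if (nrow(xs$consensus)) {
    cand <- tryCatch(
      delineate_candidates(xs$consensus$chrom[1], xs$consensus$start[1],
                           xs$consensus$end[1], records[[1]], gm$genes,
                           urr_len = config$annotation$urr_len,
                           drr_len = config$annotation$drr_len),
      error = function(e) NULL)
    if (!is.null(cand))
      utils::write.table(cand$snps, file.path(out_dir, "candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- cand
  }
  stages <- c(stages, "annotate")
  dv <- config$diversity
  panels <- simulate_diversity_panel(dv$n_cultivated, dv$n_wild, dv$n_sites,
                                     reduction = dv$reduction,
                                     sweep_region = dv$sweep_region,
                                     seed = config$seed + 13L)
  dwin_c <- diversity_windows(panels$cultivated, window_size = dv$window)
  dwin_w <- diversity_windows(panels$wild, window_size = dv$window)
  utils::write.table(dwin_c, file.path(out_dir, "diversity_cultivated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dwin_w, file.path(out_dir, "diversity_wild.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ratio <- diversity_ratio(panels$cultivated, panels$wild, dv$sweep_region)
  stages <- c(stages, "diversity")
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("mqtlseq")),
    seed = config$seed,
    parameters = config,
    stages = stages,
    diversity_ratio_pct = ratio$ratio_pct,
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results <- list(calls = calls, consensus = xs, candidates = ann,
                  diversity = list(cultivated = dwin_c, wild = dwin_w,
                                   ratio = ratio))
  attr(manifest, "results") <- results
  invisible(manifest)
}
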