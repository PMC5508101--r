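#' Configuration for the synthetic RIL-bulk data generator
#'
#' Defaults emulate the study design the pipeline targets: an F9 RIL
#' population of 260 individuals from a biparental cross, markers every
#' 5 kb along a 55-Mb chromosome-4-like pseudomolecule, two planted
#' additive flowering-time QTLs whose effects sum to the parental
#' difference (~42 days between early and late parents), ~30x mean read
#' depth, and 10-individual extreme bulks.
#'
#' @param n_ril Number of RIL individuals.
#' @param generation Selfing generation (F9 means 8 rounds of selfing after
#'   the F1).
#' @param chrom_lengths Named integer vector, chromosome -> length (bp).
#' @param marker_spacing Distance between simulated SNP markers (bp).
#' @param qtls Data frame with columns `chrom`, `pos` (bp), `effect`
#'   (additive effect in days per allele; genotype contributes
#'   `effect * (dosage - 1)`).
#' @param h2 Target entry-mean broad-sense heritability (0-1).
#' @param depth_mean Mean sequencing depth per SNP per sample (Poisson).
#' @param bulk_size Individuals per extreme bulk.
#' @param recomb_rate Recombination rate in cM/Mb (Haldane,
#'   interference-free).
#' @param baseline Trait baseline in days (value of a genotype with
#'   dosage 1 at every QTL).
#' @param noise_sd Residual SD (days) used only when there is no genetic
#'   variance to scale against (e.g. a null genome with no QTLs).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_ril = 260L,
                       generation = 9L,
                       chrom_lengths = c(chr4 = 55e6),
                       marker_spacing = 5000L,
                       qtls = data.frame(chrom = "chr4",
                                         pos = c(27.1e6, 46.4e6),
                                         effect = c(9, 12)),
                       h2 = 0.8,
                       depth_mean = 30,
                       bulk_size = 10L,
                       recomb_rate = 3,
                       baseline = 64,
                       noise_sd = 5) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome in config")
  if (bulk_size > n_ril / 2) stop("bulk_size must be <= n_ril/2")
  if (nrow(qtls)) {
    if (!all(qtls$chrom %in% names(chrom_lengths)))
      stop("QTL on unknown chromosome")
    if (any(qtls$pos < 1 | qtls$pos > chrom_lengths[qtls$chrom]))
      stop("QTL position outside chromosome")
  }
  structure(list(n_ril = as.integer(n_ril), generation = as.integer(generation),
                 chrom_lengths = chrom_lengths,
                 marker_spacing = as.integer(marker_spacing),
                 qtls = qtls, h2 = h2, depth_mean = depth_mean,
                 bulk_size = as.integer(bulk_size), recomb_rate = recomb_rate,
                 baseline = baseline, noise_sd = noise_sd),
            class = "sim_config")
}

# one meiotic gamete from haplotype pair (h1, h2) at marker positions pos
# crossover count ~ Poisson(length_Mb * cM_per_Mb / 100), Haldane
sim_gamete <- function(h1, h2, pos, chrom_len, recomb_rate) {
  n_xo <- stats::rpois(1L, chrom_len / 1e6 * recomb_rate / 100)
  phase <- sample.int(2L, 1L) - 1L
  if (n_xo == 0L) {
    if (phase == 0L) return(h1) else return(h2)
  }
  xo <- sort(stats::runif(n_xo, 0, chrom_len))
  seg <- (findInterval(pos, xo) + phase) %% 2L
  ifelse(seg == 0L, h1, h2)
}

#' Simulate an F-generation RIL population by single seed descent
#'
#' Each individual descends from an F1 by one meiosis per generation
#' (independent crossovers under the Haldane model) followed by selfing to
#' the configured generation. Genotypes are coded 0 (homozygous
#' early-parent), 2 (homozygous late-parent) and 1 (residual heterozygote);
#' at F9 the expected per-locus heterozygote fraction is (1/2)^8.
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed; the generator is a pure function of
#'   `(config, seed)`.
#' @return A truth set: list with `genotypes` (n_ril x n_markers integer
#'   matrix), `markers` (data frame `chrom`, `pos`), `qtls` and `config`.
#' @export
simulate_ril_population <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  marker_list <- lapply(names(config$chrom_lengths), function(ch) {
    data.frame(chrom = ch,
               pos = seq(config$marker_spacing, config$chrom_lengths[[ch]],
                         by = config$marker_spacing),
               stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, marker_list)
  n_mark <- nrow(markers)
  geno <- matrix(0L, nrow = config$n_ril, ncol = n_mark)
  n_self <- config$generation - 1L
  for (i in seq_len(config$n_ril)) {
    hap <- integer(0); hap2 <- integer(0)
    for (ch in names(config$chrom_lengths)) {
      idx <- which(markers$chrom == ch)
      pos <- markers$pos[idx]
      L <- config$chrom_lengths[[ch]]
      h1 <- rep(0L, length(idx)); h2 <- rep(1L, length(idx))  # F1
      for (g in seq_len(n_self)) {
        g1 <- sim_gamete(h1, h2, pos, L, config$recomb_rate)
        g2 <- sim_gamete(h1, h2, pos, L, config$recomb_rate)
        h1 <- g1; h2 <- g2
      }
      hap <- c(hap, h1); hap2 <- c(hap2, h2)
    }
    geno[i, ] <- hap + hap2
  }
  rownames(geno) <- sprintf("RIL%04d", seq_len(config$n_ril))
  list(genotypes = geno, markers = markers, qtls = config$qtls, config = config)
}

# indices of markers nearest to each configured QTL
qtl_marker_index <- function(truth) {
  if (!nrow(truth$qtls)) return(integer(0))
  vapply(seq_len(nrow(truth$qtls)), function(i) {
    on_chr <- which(truth$markers$chrom == truth$qtls$chrom[i])
    on_chr[which.min(abs(truth$markers$pos[on_chr] - truth$qtls$pos[i]))]
  }, integer(1))
}

#' Simulate replicated multi-environment phenotypes
#'
#' Trait value = baseline + sum of additive QTL effects x (dosage - 1)
#' + environment main effect + genotype-by-environment deviation +
#' residual. Non-genetic variance components are scaled so the expected
#' entry-mean broad-sense heritability equals `config$h2`:
#' with v = sigma2_g (1 - h2)/h2, sigma2_ge = 0.25 v E and
#' sigma2_e = 0.75 v E R, so sigma2_ge/E + sigma2_e/(E R) = v.
#'
#' @param truth Truth set from [simulate_ril_population()].
#' @param config The [sim_config()] used.
#' @param environments Data frame with columns `env` (label), `effect`
#'   (days added to every individual in that environment) and `n_rep`.
#'   Default: two environments with effects 0 and 2 days, two replicates.
#' @param include_parents Add observations for the two parental lines
#'   (`role` column distinguishes `ril` / `parent_early` / `parent_late`).
#' @param seed Optional RNG seed.
#' @return Long-format phenotype data frame: `individual`, `role`, `env`,
#'   `rep`, `dtf` (days to 50% flowering).
#' @export
simulate_phenotypes <- function(truth, config = truth$config,
                                environments = data.frame(
                                  env = c("field_loc1", "field_loc2"),
                                  effect = c(0, 2), n_rep = 2L),
                                include_parents = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qi <- qtl_marker_index(truth)
  gval <- rep(config$baseline, nrow(truth$genotypes))
  if (length(qi)) {
    dos <- truth$genotypes[, qi, drop = FALSE]
    gval <- gval + as.vector((dos - 1) %*% truth$qtls$effect)
  }
  sigma2_g <- stats::var(gval)
  E <- nrow(environments)
  R <- environments$n_rep[1]
  if (any(environments$n_rep != R))
    stop("unequal replicate numbers across environments are not supported")
  if (sigma2_g > 0) {
    v <- sigma2_g * (1 - config$h2) / config$h2
    sd_ge <- sqrt(0.25 * v * E)
    sd_e <- sqrt(0.75 * v * E * R)
  } else {
    sd_ge <- 0
    sd_e <- config$noise_sd
  }
  ids <- rownames(truth$genotypes)
  rows <- list()
  ge_dev <- matrix(stats::rnorm(length(ids) * E, 0, sd_ge), ncol = E)
  for (j in seq_len(E)) {
    for (r in seq_len(R)) {
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ids, role = "ril", env = environments$env[j], rep = r,
        dtf = gval + environments$effect[j] + ge_dev[, j] +
          stats::rnorm(length(ids), 0, sd_e),
        stringsAsFactors = FALSE)
    }
  }
  if (include_parents) {
    tot_eff <- if (nrow(truth$qtls)) sum(truth$qtls$effect) else 0
    for (nm in c("parent_early", "parent_late")) {
      pv <- config$baseline + if (nm == "parent_early") -tot_eff else tot_eff
      for (j in seq_len(E)) for (r in seq_len(R)) {
        rows[[length(rows) + 1L]] <- data.frame(
          individual = nm, role = nm, env = environments$env[j], rep = r,
          dtf = pv + environments$effect[j] + stats::rnorm(1, 0, sd_e),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Constitute extreme-phenotype bulks of homozygous individuals
#'
#' Selects the `bulk_size` lowest- and highest-trait individuals (trait
#' averaged over environments and replicates) among those carrying no
#' residual heterozygosity at markers inside the declared QTL regions;
#' this mirrors selecting homozygous extreme-tail lines for pooled
#' sequencing. Ties are broken by individual ID ascending.
#'
#' @param truth Truth set from [simulate_ril_population()].
#' @param phenotypes Phenotype table from [simulate_phenotypes()].
#' @param bulk_size Individuals per bulk.
#' @param qtl_margin Half-width (bp) of the region around each declared QTL
#'   within which homozygosity is required.
#' @return List with character vectors `early` and `late` (disjoint
#'   individual IDs, each of length `bulk_size`).
#' @export
constitute_bulks <- function(truth, phenotypes, bulk_size = truth$config$bulk_size,
                             qtl_margin = 1e6) {
  ph <- phenotypes[phenotypes$role == "ril", , drop = FALSE]
  means <- tapply(ph$dtf, ph$individual, mean)
  ids <- rownames(truth$genotypes)
  means <- means[ids]
  if (nrow(truth$qtls)) {
    in_region <- rep(FALSE, nrow(truth$markers))
    for (i in seq_len(nrow(truth$qtls))) {
      in_region <- in_region |
        (truth$markers$chrom == truth$qtls$chrom[i] &
           abs(truth$markers$pos - truth$qtls$pos[i]) <= qtl_margin)
    }
    hom <- apply(truth$genotypes[, in_region, drop = FALSE] != 1L, 1, all)
  } else {
    hom <- rep(TRUE, length(ids))
  }
  cand <- ids[hom]
  if (length(cand) < 2 * bulk_size)
    stop("insufficient homozygous extremes: need ", 2 * bulk_size,
         ", have ", length(cand))
  cm <- means[cand]
  ord <- cand[order(cm, cand)]  # stable: ties resolved by ID ascending
  early <- ord[seq_len(bulk_size)]
  late <- rev(ord)[seq_len(bulk_size)]
  list(early = sort(early), late = sort(late))
}

#' Simulate bulk and parent allele-depth tables
#'
#' For each SNP and each bulk the true alternate-allele (late-parent)
#' frequency is the mean allele dosage / 2 over bulk members; total depth
#' is Poisson(`depth_mean`) and alternate reads Binomial(depth, p).
#' Parents are sequenced as fixed homozygotes (p = 0 for the early parent,
#' which is the reference assembly, p = 1 for the late parent) under the
#' same depth model.
#'
#' @param truth Truth set.
#' @param bulks Bulk membership from [constitute_bulks()].
#' @param config The [sim_config()] used.
#' @param seed Optional RNG seed.
#' @return An `allele_counts` table with samples `parent_early`,
#'   `parent_late`, `bulk_early`, `bulk_late`, plus attribute
#'   `true_freq` (matrix of true alt frequencies per bulk).
#' @export
simulate_bulk_readcounts <- function(truth, bulks, config = truth$config,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth$markers)
  p_early <- colMeans(truth$genotypes[bulks$early, , drop = FALSE]) / 2
  p_late <- colMeans(truth$genotypes[bulks$late, , drop = FALSE]) / 2
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
  df <- data.frame(chrom = truth$markers$chrom, pos = truth$markers$pos,
                   ref = ref, alt = alt,
                   mean_bq = round(pmin(40, pmax(30, stats::rnorm(n, 36, 2))), 1),
                   stringsAsFactors = FALSE)
  sample_p <- list(parent_early = rep(0, n), parent_late = rep(1, n),
                   bulk_early = p_early, bulk_late = p_late)
  for (s in names(sample_p)) {
    depth <- stats::rpois(n, config$depth_mean)
    alt_n <- stats::rbinom(n, depth, sample_p[[s]])
    df[[paste0(s, "_ref")]] <- depth - alt_n
    df[[paste0(s, "_alt")]] <- alt_n
  }
  out <- allele_counts(df)
  attr(out, "true_freq") <- cbind(early = p_early, late = p_late)
  out
}

stop_codons <- c("TAA", "TAG", "TGA")

all_sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cod, stop_codons)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate a synthetic reference sequence with annotated gene models
#'
#' Places non-overlapping single- and two-exon genes on both strands along
#' a random chromosome sequence; every CDS starts with ATG, ends with a
#' stop codon and contains no internal stop. One forward-strand gene
#' reproduces a worked codon case: an AAT (Asn) codon whose second position
#' carries an A that an A->G substitution turns into AGT (Ser).
#'
#' @param chrom Chromosome name.
#' @param chrom_length Sequence length (bp).
#' @param n_genes Number of genes (>= 1; the first is the worked-case gene).
#' @param seed Optional RNG seed.
#' @return List with `sequence` (a [Biostrings::DNAStringSet]), `genes`
#'   (named list of `gene_model`) and `worked_case` (list `gene_id`, `pos`,
#'   `ref`, `alt` for the AAT->AGT codon).
#' @export
generate_gene_models <- function(chrom = "chr4", chrom_length = 60000L,
                                 n_genes = 6L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seq_chr <- sample(bases, chrom_length, replace = TRUE)
  sense <- all_sense_codons()
  slot_len <- chrom_length %/% n_genes
  genes <- list()
  worked_case <- NULL
  for (i in seq_len(n_genes)) {
    slot_start <- (i - 1L) * slot_len + 1L
    strand <- if (i == 1L) "+" else sample(c("+", "-"), 1L)
    n_cod <- sample(30:60, 1L)
    body <- sample(setdiff(sense, "ATG"), n_cod, replace = TRUE)
    if (i == 1L) body[10L] <- "AAT"  # worked codon case
    cds_seq <- paste0("ATG", paste(body, collapse = ""), sample(stop_codons, 1L))
    cds_nt <- strsplit(cds_seq, "")[[1]]
    n_nt <- length(cds_nt)
    two_exon <- i != 1L && stats::runif(1) < 0.5
    gstart <- slot_start + 100L
    if (two_exon) {
      cut <- 3L * sample(5:(n_cod - 5), 1L)
      intron_len <- 200L
      seg1 <- c(gstart, gstart + cut - 1L)
      seg2 <- c(seg1[2] + intron_len + 1L, seg1[2] + intron_len + (n_nt - cut))
      segs <- rbind(seg1, seg2)
    } else {
      segs <- rbind(c(gstart, gstart + n_nt - 1L))
    }
    gend <- max(segs[, 2])
    if (gend + 10L > slot_start + slot_len) stop("gene does not fit slot")
    # embed CDS sequence into the chromosome, strand-aware
    if (strand == "+") {
      off <- 0L
      for (k in seq_len(nrow(segs))) {
        len <- segs[k, 2] - segs[k, 1] + 1L
        seq_chr[segs[k, 1]:segs[k, 2]] <- cds_nt[(off + 1L):(off + len)]
        off <- off + len
      }
    } else {
      # transcription runs right to left: first CDS chunk occupies the
      # rightmost segment, reverse-complemented
      off <- 0L
      for (k in rev(seq_len(nrow(segs)))) {
        len <- segs[k, 2] - segs[k, 1] + 1L
        chunk <- paste(cds_nt[(off + 1L):(off + len)], collapse = "")
        seq_chr[segs[k, 1]:segs[k, 2]] <- strsplit(revcomp(chunk), "")[[1]]
        off <- off + len
      }
    }
    gid <- sprintf("gene%02d", i)
    genes[[gid]] <- gene_model(gid, chrom, strand,
                               start = gstart, end = gend,
                               cds_start = segs[, 1], cds_end = segs[, 2])
    if (i == 1L) {
      # codon 11 (body index 10 after ATG), second position, forward strand
      worked_case <- list(gene_id = gid,
                          pos = gstart + 10L * 3L + 1L,
                          ref = "A", alt = "G")
    }
  }
  dna <- Biostrings::DNAStringSet(paste(seq_chr, collapse = ""))
  names(dna) <- chrom
  list(sequence = dna, genes = genes, worked_case = worked_case)
}

#' Simulate cultivated and wild diversity panels with a local sweep
#'
#' Wild haplotypes carry unlinked biallelic sites whose derived-allele
#' counts follow the neutral folded site-frequency spectrum (P(i)
#' proportional to 1/i), so Tajima's D is centred near zero. The
#' cultivated panel is produced by a founder bottleneck (resampling from a
#' founder subset of wild haplotypes); inside `sweep_region` additional
#' per-site fixation is applied so the realized cultivated/wild
#' nucleotide-diversity ratio inside the region is about `1 - reduction`.
#'
#' @param n_cultivated,n_wild Haplotype counts per panel.
#' @param n_sites Number of biallelic sites.
#' @param reduction Target fractional diversity loss inside the sweep
#'   region (0-1).
#' @param sweep_region Length-2 vector `c(start, end)` in bp.
#' @param site_spacing Distance between consecutive sites (bp).
#' @param n_founder Founder haplotypes for the bottleneck.
#' @param seed Optional RNG seed.
#' @return List with elements `cultivated` and `wild`, each a
#'   `haplotype_matrix` (see [haplotype_matrix()]).
#' @export
simulate_diversity_panel <- function(n_cultivated = 50L, n_wild = 50L,
                                     n_sites = 2000L, reduction = 0,
                                     sweep_region = c(1, 1), site_spacing = 500L,
                                     n_founder = 25L, seed = NULL) {
  if (reduction < 0 || reduction > 1) stop("reduction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  positions <- seq(site_spacing, by = site_spacing, length.out = n_sites)
  no_overlap <- sweep_region[1] > max(positions) || sweep_region[2] < min(positions)
  if (reduction > 0 && no_overlap) stop("sweep_region outside simulated sites")
  sfs_p <- 1 / seq_len(n_wild - 1L)
  counts <- sample.int(n_wild - 1L, n_sites, replace = TRUE, prob = sfs_p)
  wild <- matrix(0L, nrow = n_wild, ncol = n_sites)
  for (j in seq_len(n_sites)) {
    wild[sample.int(n_wild, counts[j]), j] <- 1L
  }
  founders <- wild[sample.int(n_wild, min(n_founder, n_wild)), , drop = FALSE]
  cult <- founders[sample.int(nrow(founders), n_cultivated, replace = TRUE), ,
                   drop = FALSE]
  in_sweep <- positions >= sweep_region[1] & positions <= sweep_region[2]
  bottleneck_factor <- 1 - 1 / nrow(founders)
  loss <- max(0, 1 - (1 - reduction) / bottleneck_factor)
  if (loss > 0 && any(in_sweep)) {
    fix <- in_sweep & stats::runif(n_sites) < loss
    for (j in which(fix)) {
      major <- as.integer(mean(cult[, j]) >= 0.5)
      cult[, j] <- major
    }
  }
  list(cultivated = haplotype_matrix(cult, positions, label = "cultivated"),
       wild = haplotype_matrix(wild, positions, label = "wild"))
}
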