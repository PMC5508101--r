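#' Read a per-sample allele-depth table
#'
#' Loads the variant table the pipeline consumes: one row per biallelic SNP
#' with per-sample reference/alternate read depths. Two dialects are
#' supported: a plain TSV with header
#' `chrom, pos, ref, alt[, mean_bq], <sample>_ref, <sample>_alt, ...`,
#' or a VCF v4.x whose genotype fields carry `AD` (ref,alt allele depths).
#' Multiallelic and indel VCF records are skipped with a counted warning;
#' only biallelic SNPs enter the table.
#'
#' @param path Path to the TSV or VCF file.
#' @param format `"tsv"` or `"vcf"`. Defaults to guessing from the file
#'   extension (`.vcf`/`.vcf.gz` means VCF).
#' @return An `allele_counts` object: a `data.frame` with columns `chrom`,
#'   `pos` (1-based bp), `ref`, `alt`, `mean_bq` and per-sample
#'   `<sample>_ref`/`<sample>_alt` depth columns, sorted by `(chrom, pos)`,
#'   with the sample names in `attr(, "samples")`.
#' @details Internal coordinates are 1-based inclusive throughout the
#'   package; only BED export is 0-based. Duplicate `(chrom, pos)` rows are
#'   rejected; unsorted input is sorted with a warning.
#' @export
read_allele_counts <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE)
    allele_counts(df)
  } else {
    read_allele_counts_vcf(path)
  }
}

#' Construct and validate an allele-count table
#'
#' @param df Data frame with columns `chrom`, `pos`, `ref`, `alt`, optional
#'   `mean_bq`, and paired `<sample>_ref`/`<sample>_alt` depth columns.
#' @return A validated `allele_counts` data frame sorted by `(chrom, pos)`.
#' @export
allele_counts <- function(df) {
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("allele-count table missing column(s): ",
                         paste(miss, collapse = ", "))
  depth_cols <- grep("_(ref|alt)$", names(df), value = TRUE)
  samples <- unique(sub("_(ref|alt)$", "", depth_cols))
  if (!length(samples)) stop("no per-sample *_ref/*_alt depth columns found")
  for (s in samples) {
    for (suf in c("_ref", "_alt")) {
      col <- paste0(s, suf)
      if (!col %in% names(df)) stop("missing allele-depth column: ", col)
      if (any(is.na(df[[col]])) || any(df[[col]] < 0))
        stop("negative or missing depths in column ", col)
    }
  }
  if (!"mean_bq" %in% names(df)) df$mean_bq <- NA_real_
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  bad <- !(df$ref %in% c("A", "C", "G", "T")) | !(df$alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("non-ACGT ref/alt allele at row(s): ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    stop("duplicate position(s): ",
         paste(utils::head(key[duplicated(key)], 5), collapse = "; "))
  }
  o <- order(df$chrom, df$pos)
  if (is.unsorted(o) || any(o != seq_len(nrow(df)))) {
    if (!identical(o, seq_len(nrow(df)))) {
      warning("input not sorted by (chrom, pos); sorting")
      df <- df[o, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  first <- c("chrom", "pos", "ref", "alt", "mean_bq")
  df <- df[c(first, setdiff(names(df), first))]
  attr(df, "samples") <- samples
  class(df) <- c("allele_counts", "data.frame")
  df
}

read_allele_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  snp <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!snp)
  if (n_skip > 0)
    warning("skipped ", n_skip, " non-biallelic-SNP record(s)")
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  fmt <- v@gt[snp, 1]
  if (!all(grepl("AD", fmt)))
    stop("VCF record without AD allele-depth field, first at ",
         fix$CHROM[snp][which(!grepl("AD", fmt))[1]], ":",
         fix$POS[snp][which(!grepl("AD", fmt))[1]])
  ad <- vcfR::extract.gt(v, element = "AD")[snp, , drop = FALSE]
  if (any(is.na(ad)))
    stop("missing AD value(s) in VCF ", path)
  samples <- colnames(ad)
  df <- data.frame(chrom = fix$CHROM[snp], pos = as.integer(fix$POS[snp]),
                   ref = ref[snp], alt = alt[snp],
                   mean_bq = suppressWarnings(as.numeric(fix$QUAL[snp])),
                   stringsAsFactors = FALSE)
  for (s in samples) {
    parts <- strsplit(ad[, s], ",", fixed = TRUE)
    bad <- lengths(parts) < 2L
    if (any(bad))
      stop("malformed AD for sample ", s, " at ",
           df$chrom[which(bad)[1]], ":", df$pos[which(bad)[1]])
    df[[paste0(s, "_ref")]] <- as.integer(vapply(parts, `[`, "", 1L))
    df[[paste0(s, "_alt")]] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  allele_counts(df)
}

#' Write an allele-count table as TSV
#'
#' @param counts An `allele_counts` table.
#' @param path Output path.
#' @export
write_allele_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `CDS` features, grouping CDS segments under their
#' parent gene and ordering them 5'->3' on the coding strand.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @return A named list of `gene_model` objects (see [gene_model()]).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  genes_df <- df[df$type == "gene", , drop = FALSE]
  cds_df <- df[df$type == "CDS", , drop = FALSE]
  gene_ids <- as.character(genes_df$ID)
  parent_of <- function(p) {
    if (is.null(p) || length(p) == 0) return(NA_character_)
    as.character(p)[1]
  }
  cds_parent <- vapply(cds_df$Parent, parent_of, "")
  orphan <- !(cds_parent %in% gene_ids)
  if (any(orphan))
    stop("CDS feature without parent gene: parent '", cds_parent[which(orphan)[1]], "'")
  models <- lapply(seq_len(nrow(genes_df)), function(i) {
    gid <- gene_ids[i]
    seg <- cds_df[cds_parent == gid, c("start", "end"), drop = FALSE]
    gene_model(gene_id = gid,
               chrom = as.character(genes_df$seqnames[i]),
               strand = as.character(genes_df$strand[i]),
               start = genes_df$start[i], end = genes_df$end[i],
               cds_start = seg$start, cds_end = seg$end)
  })
  names(models) <- gene_ids
  models
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive gene span.
#' @param cds_start,cds_end Vectors of CDS segment bounds (1-based
#'   inclusive, any order; stored in transcription order).
#' @return A `gene_model` list with fields `gene_id`, `chrom`, `strand`,
#'   `start`, `end` and `cds` (data frame of segments in 5'->3'
#'   transcription order).
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, cds_start, cds_end) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-' for gene ", gene_id)
  if (length(cds_start) != length(cds_end))
    stop("cds_start/cds_end length mismatch for gene ", gene_id)
  cds <- data.frame(start = as.integer(cds_start), end = as.integer(cds_end))
  if (nrow(cds)) {
    if (any(cds$start > cds$end)) stop("inverted CDS segment in gene ", gene_id)
    if (any(cds$start < start | cds$end > end))
      stop("CDS outside gene span in gene ", gene_id)
    cds <- cds[order(cds$start), , drop = FALSE]
    if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)]))
      stop("overlapping CDS segments in gene ", gene_id)
    if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
    rownames(cds) <- NULL
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end), cds = cds),
            class = "gene_model")
}

#' Total CDS length of a gene model
#' @param gene A `gene_model`.
#' @return Integer length in bp.
#' @export
cds_length <- function(gene) {
  if (!nrow(gene$cds)) return(0L)
  sum(gene$cds$end - gene$cds$start + 1L)
}

#' Write gene models as GFF3
#'
#' @param models List of `gene_model` objects.
#' @param path Output GFF3 path.
#' @export
write_gene_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in models) {
    writeLines(paste(g$chrom, "mqtlseq", "gene", g$start, g$end, ".",
                     g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"), con)
    cds <- g$cds[order(g$cds$start), , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      writeLines(paste(g$chrom, "mqtlseq", "CDS", cds$start[i], cds$end[i],
                       ".", g$strand, "0",
                       paste0("ID=", g$gene_id, ".cds", i, ";Parent=", g$gene_id),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write QTL intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' rows are written as `chrom, start-1, end`.
#'
#' @param intervals Data frame with columns `chrom`, `start_snp_pos`,
#'   `end_snp_pos` and optionally `population`, `peak_delta` (as produced by
#'   [call_qtls()]), or `chrom`, `start`, `end`.
#' @param path Output BED path.
#' @export
write_intervals <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore", con)
  if (nrow(intervals)) {
    start <- if ("start_snp_pos" %in% names(intervals)) intervals$start_snp_pos else intervals$start
    end <- if ("end_snp_pos" %in% names(intervals)) intervals$end_snp_pos else intervals$end
    name <- if ("population" %in% names(intervals)) as.character(intervals$population) else "."
    score <- if ("peak_delta" %in% names(intervals)) intervals$peak_delta else 0
    writeLines(paste(intervals$chrom, format(start - 1L, scientific = FALSE, trim = TRUE),
                     format(end, scientific = FALSE, trim = TRUE),
                     name, score, sep = "\t"), con)
  }
  invisible(path)
}

#' Read intervals from a BED file written by [write_intervals()]
#'
#' @param path BED path.
#' @return Data frame with 1-based inclusive `chrom`, `start_snp_pos`,
#'   `end_snp_pos`, `population`, `peak_delta`.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start_snp_pos = integer(),
                      end_snp_pos = integer(), population = character(),
                      peak_delta = numeric(), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(chrom = parts[, 1],
             start_snp_pos = as.integer(parts[, 2]) + 1L,
             end_snp_pos = as.integer(parts[, 3]),
             population = if (ncol(parts) >= 4) parts[, 4] else ".",
             peak_delta = if (ncol(parts) >= 5) as.numeric(parts[, 5]) else 0,
             stringsAsFactors = FALSE)
}

#' Average SNP map density
#'
#' Genome span divided by SNP count, i.e. mean spacing between consecutive
#' SNPs, reported in kb to two decimals.
#'
#' @param genome_mb Genome (or chromosome) size in Mb.
#' @param n_snps Number of SNPs mapped on that span.
#' @return Density in kb per SNP, rounded to two decimals.
#' @export
map_density_kb <- function(genome_mb, n_snps) {
  if (n_snps <= 0) stop("n_snps must be positive")
  round(genome_mb * 1e6 / n_snps / 1e3, 2)
}

#' Percentage share of SNPs on one chromosome
#'
#' @param n_chrom SNPs on the chromosome.
#' @param n_total SNPs genome-wide.
#' @return Percentage rounded to one decimal.
#' @export
chrom_share_pct <- function(n_chrom, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  round(100 * n_chrom / n_total, 1)
}
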