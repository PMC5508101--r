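#' Classify SNP positions by genomic context
#'
#' Categories: `CDS` (inside a coding segment), `intron` (inside the gene
#' span but not CDS; untranslated gene sequence is not modelled
#' separately), `URR` (upstream regulatory region: within `urr_len` bp
#' 5' of the gene, strand-aware), `DRR` (downstream regulatory region:
#' within `drr_len` bp 3' of the gene), otherwise `intergenic`.
#' Precedence on ambiguity: CDS > intron > URR > DRR > intergenic;
#' overlapping URR/DRR of different genes resolve to the nearest gene,
#' ties to the lexicographically lower gene ID.
#'
#' @param pos Vector of 1-based positions (single chromosome assumed; all
#'   gene models on other chromosomes are ignored per position).
#' @param gene_models Named list of `gene_model` objects.
#' @param urr_len,drr_len Regulatory window lengths (bp, inclusive).
#' @param chrom Optional chromosome of the positions; defaults to the
#'   chromosome of the first gene model.
#' @param chrom_length Optional bound for validating positions.
#' @return Data frame with `pos`, `category`, `gene_id` (`NA` for
#'   intergenic).
#' @export
classify_location <- function(pos, gene_models, urr_len = 2000,
                              drr_len = 2000, chrom = NULL,
                              chrom_length = NULL) {
  if (is.null(chrom) && length(gene_models)) chrom <- gene_models[[1]]$chrom
  if (!is.null(chrom_length) && any(pos < 1 | pos > chrom_length))
    stop("position outside chromosome bounds")
  models <- Filter(function(g) is.null(chrom) || g$chrom == chrom, gene_models)
  one <- function(p) {
    best_reg <- NULL  # list(cat, gene, dist)
    for (g in models) {
      if (p >= g$start && p <= g$end) {
        in_cds <- any(p >= g$cds$start & p <= g$cds$end)
        return(c(if (in_cds) "CDS" else "intron", g$gene_id))
      }
      if (g$strand == "+") {
        urr <- c(g$start - urr_len, g$start - 1L)
        drr <- c(g$end + 1L, g$end + drr_len)
      } else {
        urr <- c(g$end + 1L, g$end + urr_len)
        drr <- c(g$start - drr_len, g$start - 1L)
      }
      dist <- min(abs(p - g$start), abs(p - g$end))
      for (cat in c("URR", "DRR")) {
        win <- if (cat == "URR") urr else drr
        if (p >= win[1] && p <= win[2]) {
          better <- is.null(best_reg) ||
            (cat == "URR" && best_reg$cat == "DRR") ||
            (cat == best_reg$cat &&
               (dist < best_reg$dist ||
                  (dist == best_reg$dist && g$gene_id < best_reg$gene)))
          if (better) best_reg <- list(cat = cat, gene = g$gene_id, dist = dist)
        }
      }
    }
    if (!is.null(best_reg)) return(c(best_reg$cat, best_reg$gene))
    c("intergenic", NA_character_)
  }
  res <- vapply(pos, one, character(2))
  data.frame(pos = pos, category = res[1, ], gene_id = res[2, ],
             stringsAsFactors = FALSE)
}

# spliced CDS sequence of a gene (5'->3' on the coding strand)
spliced_cds <- function(gene, ref_seq) {
  chr <- ref_seq[[gene$chrom]]
  segs <- gene$cds[order(gene$cds$start), , drop = FALSE]
  chunks <- lapply(seq_len(nrow(segs)), function(k)
    Biostrings::subseq(chr, segs$start[k], segs$end[k]))
  plus <- do.call(Biostrings::xscat, chunks)
  if (gene$strand == "+") plus else Biostrings::reverseComplement(plus)
}

# CDS coordinate (1-based, 5'->3') of a genomic position inside the CDS
cds_offset <- function(gene, pos) {
  segs <- gene$cds  # stored in transcription order
  off <- 0L
  for (k in seq_len(nrow(segs))) {
    len <- segs$end[k] - segs$start[k] + 1L
    if (pos >= segs$start[k] && pos <= segs$end[k]) {
      within <- if (gene$strand == "+") pos - segs$start[k] + 1L
                else segs$end[k] - pos + 1L
      return(off + within)
    }
    off <- off + len
  }
  NA_integer_
}

complement_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Coding effect of a SNP
#'
#' Locates the codon containing the position within the gene's spliced
#' CDS, substitutes the alternate base (strand-aware) and translates both
#' codons with the standard genetic code. The effect is `synonymous` when
#' the amino acids are equal, `nonsense` when the alternate codon is a
#' stop (TAA/TAG/TGA), otherwise `missense`.
#'
#' @param pos Genomic position (1-based, plus-strand coordinates).
#' @param ref_base,alt_base Reference and alternate bases on the plus
#'   strand.
#' @param gene A `gene_model` whose CDS contains `pos`.
#' @param ref_seq A [Biostrings::DNAStringSet] holding the chromosome.
#' @return List: `effect`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `codon_index`, `codon_pos`, `gene_id`.
#' @export
coding_effect <- function(pos, ref_base, alt_base, gene, ref_seq) {
  off <- cds_offset(gene, pos)
  if (is.na(off)) stop("position ", pos, " is not inside the CDS of gene ",
                       gene$gene_id)
  chr_base <- as.character(Biostrings::subseq(ref_seq[[gene$chrom]], pos, pos))
  if (chr_base != ref_base)
    stop("reference mismatch at ", gene$chrom, ":", pos, " (sequence ",
         chr_base, ", table ", ref_base, ")")
  cds <- as.character(spliced_cds(gene, ref_seq))
  codon_index <- (off - 1L) %/% 3L + 1L
  codon_pos <- (off - 1L) %% 3L + 1L
  ref_codon <- substr(cds, (codon_index - 1L) * 3L + 1L, codon_index * 3L)
  coding_alt <- if (gene$strand == "+") alt_base else
    complement_base[[alt_base]]
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- coding_alt
  code <- Biostrings::GENETIC_CODE
  ref_aa <- code[[ref_codon]]
  alt_aa <- code[[alt_codon]]
  effect <- if (alt_aa == "*" && ref_aa != "*") "nonsense"
            else if (ref_aa == alt_aa) "synonymous"
            else "missense"
  list(effect = effect, ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, codon_index = codon_index,
       codon_pos = codon_pos, gene_id = gene$gene_id)
}

#' Annotate a SNP table against gene models and a reference sequence
#'
#' @param counts An `allele_counts` table (or any data frame with `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param gene_models Named list of `gene_model` objects.
#' @param ref_seq [Biostrings::DNAStringSet] reference (needed for coding
#'   effects; pass `NULL` to annotate location only).
#' @param urr_len,drr_len Regulatory window lengths.
#' @return Data frame of annotated SNPs: `chrom`, `pos`, `category`,
#'   `gene_id`, `coding_effect`, `ref_aa`, `alt_aa` (`NA` outside CDS).
#' @export
annotate_snps <- function(counts, gene_models, ref_seq = NULL,
                          urr_len = 2000, drr_len = 2000) {
  cls <- classify_location(counts$pos, gene_models, urr_len, drr_len)
  out <- data.frame(chrom = counts$chrom, pos = counts$pos,
                    category = cls$category, gene_id = cls$gene_id,
                    coding_effect = NA_character_, ref_aa = NA_character_,
                    alt_aa = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(ref_seq)) {
    for (i in which(out$category == "CDS")) {
      eff <- coding_effect(out$pos[i], counts$ref[i], counts$alt[i],
                           gene_models[[out$gene_id[i]]], ref_seq)
      out$coding_effect[i] <- eff$effect
      out$ref_aa[i] <- eff$ref_aa
      out$alt_aa[i] <- eff$alt_aa
    }
  }
  out
}

#' Summarize an annotated SNP table
#'
#' Counts and percentages (one decimal) per location category, the
#' genic/intergenic split, and the synonymous/missense/nonsense split of
#' coding SNPs.
#'
#' @param annotated Output of [annotate_snps()].
#' @return List of data frames `by_category`, `genic_split`,
#'   `coding_split`, each with `class`, `n`, `pct`.
#' @export
summarize_annotation <- function(annotated) {
  pct_table <- function(x, levels) {
    n <- vapply(levels, function(l) sum(x == l, na.rm = TRUE), integer(1))
    tot <- sum(n)
    data.frame(class = levels, n = n,
               pct = if (tot > 0) round(100 * n / tot, 1) else rep(NA_real_, length(n)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  cats <- c("CDS", "intron", "URR", "DRR", "intergenic")
  by_cat <- pct_table(annotated$category, cats)
  genic <- ifelse(annotated$category == "intergenic", "intergenic", "genic")
  genic_split <- pct_table(genic, c("genic", "intergenic"))
  coding <- annotated$coding_effect[annotated$category == "CDS"]
  coding_split <- pct_table(coding, c("synonymous", "missense", "nonsense"))
  list(by_category = by_cat, genic_split = genic_split,
       coding_split = coding_split)
}
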