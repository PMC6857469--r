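#' SNP consequence classification against a gene model
#'
#' Each SNP inside a gene (or its upstream window) receives exactly one
#' category, with precedence
#' splice_region > (missense | synonymous) > utr5/utr3 > intron > upstream.
#' A SNP falling in the body of one gene and the upstream window of
#' another is assigned to the gene body. Coding SNPs are translated
#' codon-aware on the coding strand (reverse complement for minus-strand
#' genes) under the standard genetic code; a coding change to a stop codon
#' is reported as missense (no separate stop category is kept).
#'
#' @name consequence
NULL

CONSEQUENCE_CLASSES <- c("upstream", "utr5", "intron", "splice_region",
                         "synonymous", "missense", "utr3")

#' Splice-region membership of a position
#'
#' TRUE iff `pos` lies within 1-3 bases into an exon or 1-8 bases into an
#' intron from any exon-intron junction of the gene (the canonical 2-base
#' donor/acceptor dinucleotides are included in the 1-8 intronic window).
#'
#' @param pos genomic position.
#' @param gm a `gene_model`.
#' @return logical.
#' @export
splice_region_test <- function(pos, gm) {
  intr <- introns_of(gm)
  if (nrow(intr) == 0) return(FALSE)
  for (i in seq_len(nrow(intr))) {
    s <- intr[i, 1]; e <- intr[i, 2]
    if ((pos >= s && pos <= s + 7) || (pos >= e - 7 && pos <= e) ||
        (pos >= s - 3 && pos <= s - 1) || (pos >= e + 1 && pos <= e + 3))
      return(TRUE)
  }
  FALSE
}

#' Amino-acid change of a coding SNP
#'
#' @param pos genomic position (must lie in the CDS).
#' @param alt alternative allele (genomic forward strand).
#' @param gm a `gene_model`.
#' @param ref a `casein_reference`.
#' @return list with `ref_aa`, `alt_aa` (three-letter), `aa_pos` (precursor
#'   numbering) and `aa_mature` (precursor minus signal peptide).
#' @export
amino_acid_change <- function(pos, alt, gm, ref) {
  cpos <- coding_position(gm, pos)
  if (is.na(cpos)) stop("position ", pos, " is not in the CDS of ", gm$gene_id)
  gref <- reference_base(ref, pos)
  codon_idx <- (cpos - 1) %/% 3 + 1
  k <- (cpos - 1) %% 3 + 1
  gpos <- genomic_position(gm, (codon_idx - 1) * 3 + 1:3)
  codon <- reference_base(ref, gpos)
  if (gm$strand == "-") codon <- complement(codon)
  cod2 <- codon
  cod2[k] <- if (gm$strand == "+") alt else complement(alt)
  list(ref_aa = unname(AA3[CODON_TABLE[paste(codon, collapse = "")]]),
       alt_aa = unname(AA3[CODON_TABLE[paste(cod2, collapse = "")]]),
       aa_pos = as.integer(codon_idx),
       aa_mature = as.integer(codon_idx - gm$signal_peptide))
}

#' Classify one SNP
#'
#' @param pos genomic position.
#' @param ref_allele,alt reference and alternative allele (forward strand).
#' @param models list of `gene_model`.
#' @param reference a `casein_reference`.
#' @return list with `category`, `gene`, and for coding SNPs the amino-acid
#'   change fields of [amino_acid_change()].
#' @export
classify_variant <- function(pos, ref_allele, alt, models, reference) {
  gm <- NULL
  for (g in models) if (pos >= g$tx[1] && pos <= g$tx[2]) { gm <- g; break }
  if (is.null(gm))
    for (g in models)
      if (pos >= g$upstream[1] && pos <= g$upstream[2]) { gm <- g; break }
  if (is.null(gm))
    stop("out_of_scope: position ", pos, " outside all gene regions")
  if (reference_base(reference, pos) != ref_allele)
    stop("reference mismatch at ", pos, ": expected ",
         reference_base(reference, pos), ", got ", ref_allele)
  in_tx <- pos >= gm$tx[1] && pos <= gm$tx[2]
  if (in_tx && splice_region_test(pos, gm))
    return(list(category = "splice_region", gene = gm$gene_id))
  if (!is.na(coding_position(gm, pos))) {
    aa <- amino_acid_change(pos, alt, gm, reference)
    cat <- if (aa$ref_aa == aa$alt_aa) "synonymous" else "missense"
    return(c(list(category = cat, gene = gm$gene_id), aa))
  }
  if (in_intervals(pos, gm$utr5)) return(list(category = "utr5", gene = gm$gene_id))
  if (in_intervals(pos, gm$utr3)) return(list(category = "utr3", gene = gm$gene_id))
  if (in_tx) return(list(category = "intron", gene = gm$gene_id))
  list(category = "upstream", gene = gm$gene_id)
}

#' Classify all SNPs of a variant table
#'
#' @param variants data.frame with columns pos, ref, alt.
#' @param models list of `gene_model`.
#' @param reference a `casein_reference`.
#' @return data.frame: pos, ref, alt, gene, category, and amino-acid change
#'   columns (NA outside the CDS).
#' @export
classify_variants <- function(variants, models, reference) {
  out <- lapply(seq_len(nrow(variants)), function(i)
    classify_variant(variants$pos[i], variants$ref[i], variants$alt[i],
                     models, reference))
  data.frame(pos = variants$pos, ref = variants$ref, alt = variants$alt,
             gene = vapply(out, `[[`, character(1), "gene"),
             category = vapply(out, `[[`, character(1), "category"),
             ref_aa = vapply(out, function(x) x$ref_aa %||% NA_character_,
                             character(1)),
             alt_aa = vapply(out, function(x) x$alt_aa %||% NA_character_,
                             character(1)),
             aa_pos = vapply(out, function(x) x$aa_pos %||% NA_integer_,
                             integer(1)),
             aa_mature = vapply(out, function(x) x$aa_mature %||% NA_integer_,
                                integer(1)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SNP density per 10 kb
#'
#' @param counts numeric vector (or matrix) of SNP counts.
#' @param lengths region lengths in bp, same shape (> 0).
#' @return densities, counts / lengths * 10000, rounded to 1 decimal.
#' @export
snp_density <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("region lengths must be > 0")
  round(counts / lengths * 1e4, 1)
}

#' Per-gene density table over upstream / intron / exon regions
#'
#' Exon densities follow the convention of reporting coding variants
#' (missense + synonymous) per 10 kb of coding sequence; upstream and
#' intron densities use the respective region lengths. A `Total` row pools
#' counts and lengths over genes.
#'
#' @param classified output of [classify_variants()].
#' @param models list of `gene_model`.
#' @return numeric matrix genes (+Total) x
#'   c(upstream, intron, exon, missense, synonymous).
#' @export
density_table <- function(classified, models) {
  lens <- t(vapply(models, function(gm) {
    intr <- introns_of(gm)
    c(upstream = gm$upstream[2] - gm$upstream[1] + 1,
      intron = if (nrow(intr) == 0) 0 else sum(intr[, 2] - intr[, 1] + 1),
      exon = length(gm$cds_map))
  }, numeric(3)))
  cats <- c("upstream", "intron", "missense", "synonymous")
  cnt <- matrix(0, nrow(lens), 4, dimnames = list(rownames(lens), cats))
  for (g in rownames(lens))
    for (cc in cats)
      cnt[g, cc] <- sum(classified$gene == g & classified$category == cc)
  out <- cbind(
    upstream = snp_density(cnt[, "upstream"], lens[, "upstream"]),
    intron = snp_density(cnt[, "intron"], lens[, "intron"]),
    exon = snp_density(cnt[, "missense"] + cnt[, "synonymous"], lens[, "exon"]),
    missense = snp_density(cnt[, "missense"], lens[, "exon"]),
    synonymous = snp_density(cnt[, "synonymous"], lens[, "exon"]))
  total <- c(
    snp_density(sum(cnt[, "upstream"]), sum(lens[, "upstream"])),
    snp_density(sum(cnt[, "intron"]), sum(lens[, "intron"])),
    snp_density(sum(cnt[, "missense"] + cnt[, "synonymous"]), sum(lens[, "exon"])),
    snp_density(sum(cnt[, "missense"]), sum(lens[, "exon"])),
    snp_density(sum(cnt[, "synonymous"]), sum(lens[, "exon"])))
  rbind(out, Total = total)
}
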