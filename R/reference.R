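#' Synthetic reference sequence for the casein cluster window
#'
#' Materializes a single contiguous window of contig "6" covering all four
#' casein genes and their upstream regions, so that published absolute SNP
#' positions can be used verbatim without carrying a 120-Mb chromosome.
#' The window offset is recorded in the FASTA description line
#' (`offset=<n>`): base `i` of the stored sequence is genomic position
#' `offset + i`.
#'
#' Unconstrained bases are drawn uniformly at random under `seed`. Each CDS
#' is rewritten codon-wise on its coding strand: ATG initiator, TAA
#' terminator, internal codons drawn from the 61 sense codons. The codons
#' containing the seven published missense SNPs are then pinned so that the
#' genomic reference allele translates to the published reference residue
#' and the alternative allele to the published alternative residue
#' (reverse-complemented for CSN2 on the minus strand).
#'
#' @param models gene models from [build_gene_models()].
#' @param seed integer seed; same seed gives an identical sequence.
#' @param pad flanking bases beyond the outermost feature (default 200).
#' @return object of class `casein_reference`: list with `chrom`, `offset`
#'   and `seq` (character vector of single bases).
#' @export
build_reference <- function(models, seed = 1, pad = 200) {
  lo <- min(vapply(models, function(g) min(g$tx[1], g$upstream[1]), integer(1)))
  hi <- max(vapply(models, function(g) max(g$tx[2], g$upstream[2]), integer(1)))
  offset <- lo - pad - 1
  len <- hi + pad - offset
  ref <- with_seed(seed, {
    seq <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    sense <- names(CODON_TABLE)[CODON_TABLE != "*"]
    for (gm in models) {
      ncod <- length(gm$cds_map) / 3
      codons <- c("ATG", sample(sense, ncod - 2, replace = TRUE), "TAA")
      coding <- strsplit(paste(codons, collapse = ""), "")[[1]]
      seq[gm$cds_map - offset] <-
        if (gm$strand == "+") coding else complement(coding)
    }
    seq
  })
  obj <- structure(list(chrom = "6", offset = as.integer(offset), seq = ref),
                   class = "casein_reference")
  pin_anchor_codons(obj, models)
}

# Pin the codons of the published missense SNPs and verify both alleles
# translate to the published residues; abort naming the offending rule.
pin_anchor_codons <- function(ref, models) {
  anchors <- unique(casein_snp_table()[, c("gene", "pos", "ref", "alt",
                                           "aa_ref", "aa_alt", "aa_pos")])
  codon_for <- c(`87157262` = "GAA",  # Glu207, SNP at base 2 (A->G: Gly)
                 `87181619` = "CAC",  # His82,  SNP at base 2 (coding A->C: Pro)
                 `87181542` = "ATG",  # Met108, SNP at base 1 (coding A->C: Leu)
                 `87266177` = "TCT",  # Ser23,  SNP at base 2 (C->T: Phe)
                 `87390576` = "ATT",  # Ile157, SNP at base 2 (T->C: Thr)
                 `87390612` = "GCC",  # Ala169, SNP at base 2 (C->A: Asp)
                 `87390632` = "AGC")  # Ser176, SNP at base 1 (A->G: Gly)
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    gm <- models[[a$gene]]
    cpos <- coding_position(gm, a$pos)
    if (is.na(cpos))
      stop("anchor SNP ", a$pos, " not in CDS of ", a$gene)
    codon_idx <- (cpos - 1) %/% 3 + 1
    gpos <- genomic_position(gm, (codon_idx - 1) * 3 + 1:3)
    codon <- strsplit(codon_for[[as.character(a$pos)]], "")[[1]]
    ref$seq[gpos - ref$offset] <-
      if (gm$strand == "+") codon else complement(codon)
    # verify both alleles against the published residues
    for (allele in c(ref = a$ref, alt = a$alt)) {
      cod <- codon
      k <- (cpos - 1) %% 3 + 1
      cod[k] <- if (gm$strand == "+") allele else complement(allele)
      aa <- AA3[CODON_TABLE[paste(cod, collapse = "")]]
      want <- if (allele == a$ref) a$aa_ref else a$aa_alt
      if (is.na(aa) || aa != want)
        stop(sprintf("infeasible codon constraint: %s pos %d allele %s gives %s, expected %s",
                     a$gene, a$pos, allele, aa, want))
    }
    if (ref$seq[a$pos - ref$offset] != a$ref)
      stop("reference allele not installed at ", a$pos)
  }
  ref
}

#' Reference base lookup
#' @param ref `casein_reference`.
#' @param pos genomic position(s).
#' @return character vector of bases.
#' @export
reference_base <- function(ref, pos) {
  i <- pos - ref$offset
  if (any(i < 1 | i > length(ref$seq))) stop("position outside reference window")
  ref$seq[i]
}

#' Write / read the reference window as FASTA
#'
#' The description line carries the window offset
#' (`>6 offset=<n> length=<len>`); [read_reference_fasta()] restores it.
#'
#' @param ref `casein_reference`.
#' @param path file path.
#' @return `path` (write) or a `casein_reference` (read).
#' @export
write_reference_fasta <- function(ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(">%s offset=%d length=%d", ref$chrom, ref$offset,
                     length(ref$seq)), con)
  s <- paste(ref$seq, collapse = "")
  starts <- seq(1, nchar(s), by = 70)
  writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  ln <- readLines(path)
  hdr <- ln[1]
  if (!startsWith(hdr, ">")) stop("not a FASTA file: ", path)
  chrom <- sub("^>(\\S+).*", "\\1", hdr)
  off <- suppressWarnings(as.integer(sub(".*offset=(-?\\d+).*", "\\1", hdr)))
  if (is.na(off)) off <- 0L
  seq <- strsplit(paste(ln[-1], collapse = ""), "")[[1]]
  structure(list(chrom = chrom, offset = off, seq = toupper(seq)),
            class = "casein_reference")
}

#' @export
print.casein_reference <- function(x, ...) {
  cat(sprintf("<casein_reference> contig %s, window %d-%d (%d bp)\n",
              x$chrom, x$offset + 1, x$offset + length(x$seq), length(x$seq)))
  invisible(x)
}
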