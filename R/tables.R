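#' Built-in tables for the bovine casein cluster
#'
#' The package ships, as plain R objects, the published per-breed summary
#' tables for the casein cluster on BTA6 that every analysis stage uses as
#' reference input: the seven missense SNPs that define the common casein
#' protein variants (with rs identifiers, alleles, amino-acid exchanges and
#' per-breed variant frequencies), the per-breed comprehensive protein
#' haplotype frequency matrix, and the per-breed sample sizes of the
#' underlying 14-breed whole-genome sequencing panel.
#'
#' @name casein-tables
NULL

#' Breed sample sizes of the 14-breed sequencing panel
#'
#' @return Named integer vector, number of sequenced animals per breed
#'   (1,821 in total).
#' @export
breed_sample_sizes <- function() {
  c(DSN = 30L, Holstein = 541L, Angus = 276L, Simmental = 217L,
    `Brown Swiss` = 148L, Charolais = 127L, Limousin = 82L, Hereford = 75L,
    Jersey = 66L, `Danish Red` = 56L, Montbeliarde = 54L, Fleckvieh = 53L,
    Gelbvieh = 52L, Normande = 44L)
}

#' Missense SNPs defining the common casein protein variants
#'
#' One row per defining SNP of the named casein variants. Positions are
#' 1-based on BTA6 (UMD3.1 numbering). `ref`/`alt` are the genomic strand
#' alleles as in the VCF; `variant_allele` is the genomic allele carried by
#' the named protein variant. Amino-acid positions are given in precursor
#' numbering (`aa_pos`) and mature-protein numbering (`aa_mature`), which
#' differ by the signal peptide length (15 residues for CSN1S1, CSN2 and
#' CSN1S2; 21 for CSN3). `freq_dsn`, `freq_hf`, `freq_all` are the published
#' per-breed variant frequencies (DSN, Holstein Friesian, all 14 breeds);
#' for multi-SNP variants the frequency is attached to every defining row.
#'
#' @return data.frame with one row per (variant, SNP) pair.
#' @export
casein_snp_table <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene   variant pos      ref alt variant_allele aa_ref aa_alt aa_pos aa_mature snp_id      freq_dsn freq_hf freq_all
CSN1S1 B       87157262 A   G   A              Glu    Gly    207    192       rs43703010  1.000    0.995   0.944
CSN2   A1      87181619 T   G   T              His    Pro    82     67        rs43703011  0.827    0.340   0.295
CSN2   A2      87181619 T   G   G              His    Pro    82     67        rs43703011  0.156    0.562   0.592
CSN2   I       87181542 T   G   G              Met    Leu    108    93        rs109299401 0.017    0.059   0.036
CSN1S2 A       87266177 C   T   C              Ser    Phe    23     8         rs441966828 1.000    1.000   0.994
CSN3   A       87390576 T   C   C              Ile    Thr    157    136       rs43703015  0.833    0.752   0.628
CSN3   A       87390612 C   A   C              Ala    Asp    169    148       rs43703016  0.833    0.752   0.628
CSN3   A       87390632 A   G   A              Ser    Gly    176    155       rs43703017  0.833    0.752   0.628
CSN3   B       87390576 T   C   T              Ile    Thr    157    136       rs43703015  0.133    0.203   0.341
CSN3   B       87390612 C   A   A              Ala    Asp    169    148       rs43703016  0.133    0.203   0.341
CSN3   B       87390632 A   G   A              Ser    Gly    176    155       rs43703017  0.133    0.203   0.341
CSN3   E       87390576 T   C   C              Ile    Thr    157    136       rs43703015  0.034    0.045   0.030
CSN3   E       87390612 C   A   C              Ala    Asp    169    148       rs43703016  0.034    0.045   0.030
CSN3   E       87390632 A   G   G              Ser    Gly    176    155       rs43703017  0.034    0.045   0.030
")
  df$pos <- as.integer(df$pos)
  df
}

#' Positions of the seven casein missense SNPs, in genomic order
#'
#' @return Sorted integer vector of the seven defining SNP positions.
#' @export
casein_snp_positions <- function() {
  sort(unique(casein_snp_table()$pos))
}

#' Signal peptide lengths of the four casein precursors
#'
#' Difference between precursor and mature amino-acid numbering.
#'
#' @return Named integer vector.
#' @export
signal_peptide_lengths <- function() {
  c(CSN1S1 = 15L, CSN2 = 15L, CSN1S2 = 15L, CSN3 = 21L)
}

#' Published comprehensive casein haplotype frequencies per breed
#'
#' The 13 named four-gene protein haplotypes (gene order
#' CSN1S1-CSN2-CSN1S2-CSN3) that reach 5\% frequency in at least one of the
#' 14 breeds, plus a pooled `Total` column and a `Residual` row collecting
#' all remaining haplotypes. Absent entries are zero.
#'
#' @param residual logical; keep the Residual row (default TRUE).
#' @param total logical; keep the pooled Total column (default TRUE).
#' @return Numeric matrix, haplotype labels x breeds.
#' @export
casein_haplotype_table <- function(residual = TRUE, total = TRUE) {
  labels <- c("B-A2-A-A", "B-A1-A-A", "B-A2-A-B", "B-A1-A-B", "B-B-A-B",
              "C-A2-A-B", "B-I-A-B", "B-A2-A-E", "C-A2-A-A", "B-B-A-A",
              "B-A2-D-B", "B-F-A-A", "B-A2-C-A", "Residual")
  breeds <- c("Total", "Limousin", "Angus", "Hereford", "Charolais",
              "Simmental", "Fleckvieh", "Normande", "Montbeliarde",
              "Brown Swiss", "Gelbvieh", "Jersey", "Danish Red",
              "Holstein", "DSN")
  m <- matrix(c(
    # Total  Limou  Angus  Heref  Charo  Simme  Fleck  Norma  Montb  BrSwi  Gelbv  Jerse  DanRe  Holst  DSN
    0.424, 0.419, 0.644, 0.359, 0.331, 0.446, 0.415, 0.100, 0.072, 0.115, 0.490, 0.045, 0.136, 0.531, 0.116,
    0.147, 0.071, 0.032, 0.313, 0.041, 0.145, 0.270, 0.046, 0.055, 0.078, 0.091, 0,     0.439, 0.196, 0.717,
    0.141, 0.196, 0.075, 0.026, 0.286, 0.178, 0.147, 0.081, 0.304, 0.500, 0.133, 0.047, 0.132, 0.056, 0.024,
    0.057, 0.105, 0.006, 0.028, 0.163, 0.081, 0,     0.062, 0.014, 0.020, 0.114, 0.124, 0.031, 0.063, 0.093,
    0.051, 0.038, 0.002, 0.238, 0.013, 0.009, 0,     0.221, 0,     0.079, 0,     0.226, 0.017, 0.027, 0,
    0.048, 0.094, 0.026, 0.007, 0.033, 0.032, 0,     0.284, 0,     0.069, 0,     0.506, 0.002, 0.001, 0,
    0.035, 0.029, 0.007, 0.007, 0,     0.020, 0,     0.162, 0.151, 0,     0,     0.052, 0,     0.061, 0.017,
    0.020, 0,     0.105, 0,     0,     0.003, 0,     0,     0,     0,     0,     0,     0.028, 0.002, 0.013,
    0.019, 0.018, 0.020, 0.023, 0.028, 0.049, 0.117, 0.020, 0.034, 0.051, 0,     0,     0,     0.002, 0,
    0.017, 0,     0,     0,     0.065, 0.030, 0.022, 0,     0.359, 0.083, 0,     0,     0,     0.001, 0,
    0.004, 0,     0,     0,     0,     0,     0,     0,     0,     0,     0.132, 0,     0.054, 0,     0,
    0.005, 0,     0,     0,     0,     0,     0,     0,     0,     0,     0,     0,     0.136, 0.003, 0,
    0.011, 0,     0.075, 0,     0,     0,     0,     0,     0,     0,     0,     0,     0,     0,     0,
    0.021, 0.030, 0.007, 0,     0.040, 0.006, 0.030, 0.023, 0.011, 0.005, 0.040, 0,     0.022, 0.057, 0.021
  ), nrow = length(labels), ncol = length(breeds), byrow = TRUE,
  dimnames = list(labels, breeds))
  if (!residual) m <- m[rownames(m) != "Residual", , drop = FALSE]
  if (!total) m <- m[, colnames(m) != "Total", drop = FALSE]
  m
}

#' Named-haplotype distribution of one breed, residual dropped
#'
#' Extracts one breed column of the published haplotype table, drops the
#' Residual mass (its composition is unpublished) and renormalizes the
#' named haplotypes to sum to one. This is the generating distribution the
#' synthetic cohort module uses by default.
#'
#' @param breed breed name (column of [casein_haplotype_table()]).
#' @return Named numeric vector summing to 1, zero entries removed.
#' @export
breed_haplotype_freqs <- function(breed) {
  tab <- casein_haplotype_table(residual = FALSE)
  if (!breed %in% colnames(tab))
    stop("unknown breed: ", breed)
  p <- tab[, breed]
  p <- p[p > 0]
  p / sum(p)
}

#' Minimum detectable allele frequency in a diploid sample
#'
#' With n diploid animals, 2n chromosomes are observed, so the smallest
#' nonzero allele frequency is 1/(2n) -- a single heterozygous animal.
#'
#' @param n number of diploid individuals.
#' @return numeric, 1 / (2 n).
#' @export
min_detectable_freq <- function(n) {
  stopifnot(n >= 1)
  1 / (2 * n)
}
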