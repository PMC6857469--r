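#' Casein protein-variant rules
#'
#' A rule maps a per-gene SNP haplotype (genomic alleles at the gene's
#' defining positions) to a named protein variant. The built-in table
#' covers the variants defined by the seven published missense SNPs:
#' CSN1S1*B; CSN2*A1, *A2, *I; CSN1S2*A; CSN3*A, *B, *E. Within a gene the
#' completed signatures are mutually exclusive over the gene's rule
#' positions, so at most one variant can match a haplotype; haplotypes
#' matching no rule are reported as "unassigned".
#'
#' The CSN2 signatures deserve a note: A1 carries His67 (T at 87181619) on
#' the reference background at 87181542; A2 carries Pro67 (G) on the same
#' background; I is an A2-derived variant additionally carrying Leu93
#' (G at 87181542). The combination T@87181619 + G@87181542 matches no
#' named variant.
#'
#' @return data.frame with columns gene, variant, pos, allele (one row per
#'   signature element), class `protein_rules`.
#' @export
builtin_rules <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene   variant pos      allele
CSN1S1 B       87157262 A
CSN2   A1      87181542 T
CSN2   A1      87181619 T
CSN2   A2      87181542 T
CSN2   A2      87181619 G
CSN2   I       87181542 G
CSN2   I       87181619 G
CSN1S2 A       87266177 C
CSN3   A       87390576 C
CSN3   A       87390612 C
CSN3   A       87390632 A
CSN3   B       87390576 T
CSN3   B       87390612 A
CSN3   B       87390632 A
CSN3   E       87390576 C
CSN3   E       87390612 C
CSN3   E       87390632 G
")
  df$pos <- as.integer(df$pos)
  validate_rules(df)
}

validate_rules <- function(rules) {
  for (g in unique(rules$gene)) {
    sub <- rules[rules$gene == g, ]
    pos <- sort(unique(sub$pos))
    sig <- vapply(split(sub, sub$variant), function(s) {
      if (!setequal(s$pos, pos))
        stop("rule for ", g, "*", s$variant[1],
             " does not cover all rule positions of ", g)
      paste(s$allele[match(pos, s$pos)], collapse = "")
    }, character(1))
    if (anyDuplicated(sig))
      stop("conflicting rules in ", g, ": identical signatures for ",
           paste(names(sig)[duplicated(sig) | duplicated(sig, fromLast = TRUE)],
                 collapse = ", "))
  }
  class(rules) <- c("protein_rules", "data.frame")
  rules
}

#' Read protein-variant rules from TSV and merge with the built-ins
#'
#' The TSV has columns gene, variant, pos, allele (one row per signature
#' element). Extension rules conflicting with a built-in signature are an
#' error.
#'
#' @param path TSV file, or NULL for built-ins only.
#' @return validated `protein_rules` data.frame.
#' @export
read_rules <- function(path = NULL) {
  rules <- builtin_rules()
  if (is.null(path)) return(rules)
  ext <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ext$pos <- as.integer(ext$pos)
  validate_rules(rbind(as.data.frame(rules), ext[, names(rules)]))
}

#' Call the protein variant of one per-gene haplotype
#'
#' @param haplotype named character vector position -> genomic allele,
#'   covering at least the gene's rule positions.
#' @param rules a `protein_rules` table.
#' @param gene gene symbol.
#' @return variant name, or "unassigned" when no signature matches.
#' @export
call_variant <- function(haplotype, rules, gene) {
  sub <- rules[rules$gene == gene, ]
  if (nrow(sub) == 0) stop("no rules for gene ", gene)
  pos <- as.character(sort(unique(sub$pos)))
  if (!all(pos %in% names(haplotype)))
    stop("haplotype does not cover rule positions ",
         paste(setdiff(pos, names(haplotype)), collapse = ", "))
  hits <- vapply(split(sub, sub$variant), function(s)
    all(haplotype[as.character(s$pos)] == s$allele), logical(1))
  if (sum(hits) > 1)
    stop("ambiguous variant match for ", gene) # unreachable given validation
  if (sum(hits) == 0) "unassigned" else names(hits)[hits]
}

#' Per-breed protein-variant frequencies from per-gene EM fits
#'
#' The frequency of a protein variant is the sum of the EM frequencies of
#' the SNP haplotypes that map to it; unmatched haplotypes are reported as
#' "unassigned", never dropped. Frequencies per gene and breed sum to 1.
#'
#' @param gm a [genotype_matrix()] with breeds attached.
#' @param rules a `protein_rules` table.
#' @param ... passed to [em_fit()].
#' @return data.frame with columns gene, variant, breed, freq; breed
#'   "Total" is the pooled fit.
#' @export
variant_frequencies <- function(gm, rules = builtin_rules(), ...) {
  out <- list()
  for (g in unique(rules$gene)) {
    pos <- sort(unique(rules$pos[rules$gene == g]))
    fits <- per_breed_frequencies(gm, pos, ...)
    cols <- c(list(Total = fits$pooled), fits$breeds)
    for (b in names(cols)) {
      fit <- cols[[b]]
      labs <- vapply(fit$haplotypes, function(h) {
        al <- stats::setNames(strsplit(fit$allele_strings[[h]], "")[[1]],
                              as.character(pos))
        call_variant(al, rules, g)
      }, character(1))
      f <- tapply(fit$freqs, factor(labs), sum)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, variant = names(f), breed = b, freq = as.numeric(f),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lay a variant-frequency data.frame out as a matrix
#'
#' @param freqs data.frame from [variant_frequencies()].
#' @return numeric matrix "gene*variant" x breeds.
#' @export
variant_frequency_table <- function(freqs) {
  lab <- paste0(freqs$gene, "*", freqs$variant)
  tab <- tapply(freqs$freq, list(factor(lab, levels = unique(lab)),
                                 factor(freqs$breed, levels = unique(freqs$breed))),
                identity)
  tab[is.na(tab)] <- 0
  tab
}
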