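#' @keywords internal
"_PACKAGE"

# Standard genetic code, codon -> one-letter amino acid ('*' = stop).
CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  codons <- character(64)
  i <- 0
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  for (p1 in b) for (p2 in b) for (p3 in b) {
    i <- i + 1
    codons[i] <- paste0(p1, p2, p3)
  }
  stats::setNames(aas, codons)
})

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

#' Translate a coding DNA sequence
#'
#' Standard genetic code; input length must be a multiple of 3.
#'
#' @param seq character scalar (coding strand) or character vector of bases.
#' @param three_letter logical, return three-letter residue names.
#' @return character vector of residues ('*'/'Ter' marks stop).
#' @export
translate_cds <- function(seq, three_letter = FALSE) {
  if (length(seq) == 1 && nchar(seq[1]) > 1) seq <- strsplit(seq, "")[[1]]
  if (length(seq) %% 3 != 0) stop("CDS length not a multiple of 3")
  codons <- paste0(seq[c(TRUE, FALSE, FALSE)], seq[c(FALSE, TRUE, FALSE)],
                   seq[c(FALSE, FALSE, TRUE)])
  aa <- unname(CODON_TABLE[codons])
  if (any(is.na(aa))) stop("non-ACGT base in CDS")
  if (three_letter) unname(AA3[aa]) else aa
}

#' Reverse complement
#' @param x character vector of bases, or a single string.
#' @return same shape as input.
#' @export
revcomp <- function(x) {
  single <- length(x) == 1 && nchar(x[1]) > 1
  if (single) x <- strsplit(x, "")[[1]]
  out <- rev(complement(x))
  if (single) paste(out, collapse = "") else out
}

#' @rdname revcomp
#' @export
complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# Run code with a temporarily fixed RNG seed; restores the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# TSV writers used across modules: plain, tab-separated, no quoting.
write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
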