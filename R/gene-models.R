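#' Gene model objects for the casein cluster
#'
#' A `gene_model` is a strand-aware description of one gene: ordered exon
#' intervals, coding intervals with reading frame, 5'/3' UTR intervals, the
#' upstream regulatory window abutting the transcript start, and the signal
#' peptide length used to convert precursor to mature protein positions.
#' All coordinates are 1-based, closed intervals on the genomic forward
#' strand, matching VCF convention and published SNP positions.
#'
#' @param gene_id gene symbol, e.g. "CSN2".
#' @param chrom contig name.
#' @param strand "+" or "-".
#' @param exons,cds,utr5,utr3 two-column matrices (start, end), rows in
#'   increasing genomic order; `utr5`/`utr3` may have zero rows.
#' @param upstream_length length of the upstream window in bp.
#' @param signal_peptide signal peptide length in residues.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds,
                       utr5 = NULL, utr3 = NULL,
                       upstream_length = 1000, signal_peptide = 0L) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  as_iv <- function(m) {
    if (is.null(m)) return(matrix(integer(0), 0, 2,
                                  dimnames = list(NULL, c("start", "end"))))
    m <- matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
    m[order(m[, 1]), , drop = FALSE]
  }
  exons <- as_iv(exons); cds <- as_iv(cds)
  utr5 <- as_iv(utr5); utr3 <- as_iv(utr3)
  if (any(exons[, 2] < exons[, 1])) stop("malformed exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons in ", gene_id)
  tx <- c(min(exons[, 1]), max(exons[, 2]))
  if (sum(cds[, 2] - cds[, 1] + 1) %% 3 != 0)
    stop("CDS length of ", gene_id, " not divisible by 3")
  # genomic positions of CDS bases in coding (5'->3') order
  cds_map <- unlist(lapply(seq_len(nrow(cds)),
                           function(i) cds[i, 1]:cds[i, 2]))
  if (strand == "-") cds_map <- rev(cds_map)
  upstream <- if (strand == "+") {
    c(tx[1] - upstream_length, tx[1] - 1)
  } else {
    c(tx[2] + 1, tx[2] + upstream_length)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tx = as.integer(tx), exons = exons, cds = cds,
                 utr5 = utr5, utr3 = utr3,
                 upstream = as.integer(upstream), cds_map = cds_map,
                 signal_peptide = as.integer(signal_peptide)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exons, CDS %d nt, upstream %d bp\n",
              x$gene_id, x$chrom, x$tx[1], x$tx[2], x$strand,
              nrow(x$exons), length(x$cds_map),
              x$upstream[2] - x$upstream[1] + 1))
  invisible(x)
}

# intron intervals (genomic order); zero-row matrix for single-exon genes
introns_of <- function(gm) {
  ex <- gm$exons
  if (nrow(ex) < 2) return(matrix(integer(0), 0, 2))
  cbind(start = ex[-nrow(ex), 2] + 1, end = ex[-1, 1] - 1)
}

in_intervals <- function(pos, iv) {
  if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= iv[, 1] & p <= iv[, 2]), logical(1))
}

# 1-based coding position of a genomic position, NA if not in CDS
coding_position <- function(gm, pos) {
  match(pos, gm$cds_map)
}

# genomic position of a 1-based coding position
genomic_position <- function(gm, cpos) {
  gm$cds_map[cpos]
}

#' Build the four casein gene models
#'
#' Returns synthetic but realistically proportioned models of CSN1S1 (+),
#' CSN2 (-), CSN1S2 (+) and CSN3 (+) on contig "6", engineered so that the
#' seven published missense SNP positions fall inside coding exons at the
#' reading-frame offsets implied by their published precursor amino-acid
#' positions (e.g. 6:87181619 is the second base of codon 82 of CSN2, read
#' on the reverse strand). Precursor lengths are the true ones (214, 224,
#' 222 and 190 codons including the initiator; signal peptides 15/15/15/21).
#'
#' @param upstream_length upstream window size in bp (default 1000).
#' @return named list of four `gene_model` objects in chromosomal order.
#' @export
build_gene_models <- function(upstream_length = 1000) {
  iv <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  m <- list(
    CSN1S1 = gene_model("CSN1S1", "6", "+",
      exons = iv(87141600, 87141649, 87143000, 87143062, 87146000, 87146099,
                 87148000, 87148120, 87152000, 87152199, 87155340, 87155400,
                 87157188, 87157487),
      cds   = iv(87143000, 87143062, 87146000, 87146099, 87148000, 87148120,
                 87152000, 87152199, 87155340, 87155400, 87157188, 87157287),
      utr5  = iv(87141600, 87141649),
      utr3  = iv(87157288, 87157487),
      upstream_length = upstream_length, signal_peptide = 15L),
    CSN2 = gene_model("CSN2", "6", "-",
      exons = iv(87180400, 87180699, 87181339, 87181713,
                 87185350, 87185499, 87189851, 87189900),
      cds   = iv(87180550, 87180699, 87181339, 87181713, 87185350, 87185499),
      utr5  = iv(87189851, 87189900),
      utr3  = iv(87180400, 87180549),
      upstream_length = upstream_length, signal_peptide = 15L),
    CSN1S2 = gene_model("CSN1S2", "6", "+",
      exons = iv(87262100, 87262149, 87266110, 87266259,
                 87270000, 87270199, 87275000, 87275518),
      cds   = iv(87266110, 87266259, 87270000, 87270199, 87275000, 87275318),
      utr5  = iv(87262100, 87262149),
      utr3  = iv(87275319, 87275518),
      upstream_length = upstream_length, signal_peptide = 15L),
    CSN3 = gene_model("CSN3", "6", "+",
      exons = iv(87378100, 87378163, 87381000, 87381059,
                 87384000, 87384059, 87390227, 87390879),
      cds   = iv(87381000, 87381059, 87384000, 87384059, 87390227, 87390679),
      utr5  = iv(87378100, 87378163),
      utr3  = iv(87390680, 87390879),
      upstream_length = upstream_length, signal_peptide = 21L)
  )
  m
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / exon / CDS / five_prime_UTR / three_prime_UTR
#' features with phase on CDS rows.
#'
#' @param models list of `gene_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  row <- function(chrom, type, s, e, strand, phase, attr)
    paste(chrom, "caseinhap", type, s, e, ".", strand, phase, attr, sep = "\t")
  for (gm in models) {
    gid <- gm$gene_id
    writeLines(row(gm$chrom, "gene", gm$tx[1], gm$tx[2], gm$strand, ".",
                   sprintf("ID=gene:%s;Name=%s", gid, gid)), con)
    writeLines(row(gm$chrom, "mRNA", gm$tx[1], gm$tx[2], gm$strand, ".",
                   sprintf("ID=transcript:%s.t1;Parent=gene:%s", gid, gid)), con)
    emit <- function(type, ivm, phased = FALSE) {
      if (nrow(ivm) == 0) return()
      rows <- seq_len(nrow(ivm))
      if (phased) {
        # phase = bases to skip before the first complete codon of each piece
        ord <- if (gm$strand == "+") rows else rev(rows)
        lens <- ivm[ord, 2] - ivm[ord, 1] + 1
        prior <- c(0, cumsum(lens))[seq_along(lens)]
        ph <- (3 - prior %% 3) %% 3
        ph <- ph[order(ord)]
      } else ph <- rep(".", nrow(ivm))
      for (i in rows)
        writeLines(row(gm$chrom, type, ivm[i, 1], ivm[i, 2], gm$strand, ph[i],
                       sprintf("Parent=transcript:%s.t1", gid)), con)
    }
    emit("exon", gm$exons)
    emit("CDS", gm$cds, phased = TRUE)
    emit("five_prime_UTR", gm$utr5)
    emit("three_prime_UTR", gm$utr3)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reads the feature types written by [write_gff3()]. Signal peptide
#' lengths are attached from [signal_peptide_lengths()] when the gene name
#' is a casein gene, else 0.
#'
#' @param path GFF3 file.
#' @param upstream_length upstream window size in bp.
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(path, upstream_length = 1000) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  if (ncol(f) != 9) stop("malformed GFF3: expected 9 columns")
  df <- data.frame(chrom = f[, 1], type = f[, 3],
                   start = as.integer(f[, 4]), end = as.integer(f[, 5]),
                   strand = f[, 7], attr = f[, 9], stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", ]
  sp <- signal_peptide_lengths()
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- sub(".*Name=([^;]+).*", "\\1", genes$attr[i])
    tid <- sprintf("transcript:%s.t1", gid)
    sub <- df[grepl(tid, df$attr, fixed = TRUE) & df$type != "mRNA", ]
    take <- function(type) {
      s <- sub[sub$type == type, c("start", "end")]
      if (nrow(s) == 0) NULL else as.matrix(s)
    }
    out[[gid]] <- gene_model(gid, genes$chrom[i], genes$strand[i],
                             exons = take("exon"), cds = take("CDS"),
                             utr5 = take("five_prime_UTR"),
                             utr3 = take("three_prime_UTR"),
                             upstream_length = upstream_length,
                             signal_peptide = if (gid %in% names(sp)) sp[[gid]] else 0L)
  }
  out[order(vapply(out, function(g) g$tx[1], integer(1)))]
}
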