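#' In-memory genotype matrix with allele depths
#'
#' Container used by all downstream stages: per-sample allele dosages
#' (count of alternative alleles, NA = missing), per-sample read depths on
#' the reference and alternative allele (NA = unknown), the variant table
#' and an optional sample -> breed map.
#'
#' @param samples character vector of sample ids (rows).
#' @param variants data.frame with columns chrom, pos, id, ref, alt.
#' @param dosage integer matrix samples x variants in \{0,1,2,NA\}.
#' @param ad_ref,ad_alt integer matrices of per-allele read counts, or NULL.
#' @param breed_of named character vector sample -> breed, or NULL.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, dosage,
                            ad_ref = NULL, ad_alt = NULL, breed_of = NULL) {
  stopifnot(nrow(dosage) == length(samples), ncol(dosage) == nrow(variants))
  if (!is.null(breed_of) && !all(samples %in% names(breed_of)))
    stop("every sample must have a breed")
  bad <- variants$ref == variants$alt |
    !(variants$ref %in% c("A", "C", "G", "T")) |
    !(variants$alt %in% c("A", "C", "G", "T")) | variants$pos < 1
  if (any(bad)) stop("invalid variant record at row ", which(bad)[1])
  rownames(dosage) <- samples
  structure(list(samples = samples, variants = variants, dosage = dosage,
                 ad_ref = ad_ref, ad_alt = ad_alt,
                 breed_of = if (is.null(breed_of)) NULL else breed_of[samples]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%s), %d breed(s)\n",
              length(x$samples), nrow(x$variants),
              sprintf("%.1f%% missing", 100 * mean(is.na(x$dosage))),
              if (is.null(x$breed_of)) 0 else length(unique(x$breed_of))))
  invisible(x)
}

# internal: write a biallelic-SNP VCF 4.2 with GT and AD
write_vcf <- function(variants, samples, dosage, ad_ref, ad_alt, chrom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=caseinhap",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele read depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  nv <- nrow(variants)
  for (j in seq_len(nv)) {
    d <- dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1])
    field <- paste0(gt, ":", ad_ref[, j], ",", ad_alt[, j])
    writeLines(paste(c(chrom, variants$pos[j], variants$id[j],
                       variants$ref[j], variants$alt[j], ".", "PASS", ".",
                       "GT:AD", field), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads biallelic SNP records with GT (and, when present, AD) FORMAT
#' fields. Multiallelic or non-SNP records, and records outside `region`,
#' are skipped; the number skipped is reported as attribute
#' `skipped` and via a message. Phased separators are accepted; phase is
#' discarded.
#'
#' @param path VCF file (plain text).
#' @param region optional "chrom:start-end" string restricting records.
#' @param breed_map optional named character vector sample -> breed.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL, breed_map = NULL) {
  ln <- readLines(path)
  hdr_i <- grep("^#CHROM", ln)
  if (length(hdr_i) != 1) stop("malformed VCF: missing #CHROM header line")
  hdr <- strsplit(ln[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) stop("no samples in VCF")
  samples <- hdr[-(1:9)]
  body_i <- which(!startsWith(ln, "#"))
  body_i <- body_i[body_i > hdr_i]
  reg <- NULL
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):(\\d+)-(\\d+)$", region))[[1]]
    if (length(m) != 4) stop("malformed region: ", region)
    reg <- list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  }
  recs <- list(); skipped <- 0L
  for (i in body_i) {
    f <- strsplit(ln[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop("malformed VCF record at line ", i, ": field count mismatch")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("malformed VCF record at line ", i, ": bad POS")
    if (grepl(",", f[5], fixed = TRUE) ||
        !(f[4] %in% c("A", "C", "G", "T")) ||
        !(f[5] %in% c("A", "C", "G", "T"))) {
      skipped <- skipped + 1L
      next
    }
    if (!is.null(reg) &&
        (f[1] != reg$chrom || pos < reg$start || pos > reg$end)) next
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_k <- match("GT", fmt); ad_k <- match("AD", fmt)
    if (is.na(gt_k)) stop("malformed VCF record at line ", i, ": no GT")
    cells <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    gt <- vapply(cells, `[`, character(1), gt_k)
    al <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
    dos <- vapply(al, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
    if (!is.na(ad_k)) {
      ad <- vapply(cells, `[`, character(1), ad_k)
      adm <- do.call(rbind, lapply(strsplit(ad, ",", fixed = TRUE), function(v) {
        if (length(v) < 2 || any(v == ".")) c(NA_integer_, NA_integer_)
        else as.integer(v[1:2])
      }))
    } else adm <- matrix(NA_integer_, length(samples), 2)
    recs[[length(recs) + 1L]] <-
      list(chrom = f[1], pos = pos, id = f[3], ref = f[4], alt = f[5],
           dos = dos, ad = adm)
  }
  if (skipped > 0)
    message(skipped, " non-biallelic-SNP record(s) skipped")
  if (length(recs) == 0) stop("no usable variant records in ", path)
  variants <- data.frame(
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    pos = vapply(recs, `[[`, integer(1), "pos"),
    id = vapply(recs, `[[`, character(1), "id"),
    ref = vapply(recs, `[[`, character(1), "ref"),
    alt = vapply(recs, `[[`, character(1), "alt"),
    stringsAsFactors = FALSE)
  dosage <- vapply(recs, `[[`, integer(length(samples)), "dos")
  ad_ref <- vapply(recs, function(r) r$ad[, 1], integer(length(samples)))
  ad_alt <- vapply(recs, function(r) r$ad[, 2], integer(length(samples)))
  dim(dosage) <- dim(ad_ref) <- dim(ad_alt) <- c(length(samples), nrow(variants))
  gm <- genotype_matrix(samples, variants, dosage, ad_ref, ad_alt, breed_map)
  attr(gm, "skipped") <- skipped
  gm
}

#' Read a sample -> breed map
#'
#' Two-column TSV (sample_id, breed), header optional. Duplicate sample ids
#' are an error.
#'
#' @param path TSV file.
#' @return named character vector sample -> breed.
#' @export
read_breed_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, col.names = c("sample", "breed"))
  if (nrow(df) > 0 && identical(tolower(df[1, 1]), "sample_id"))
    df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) stop("empty breed map: ", path)
  if (anyDuplicated(df$sample))
    stop("duplicate sample id(s) in breed map: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  stats::setNames(df$breed, df$sample)
}

#' Attach breed labels to a genotype matrix
#'
#' Errors listing any VCF sample missing from the map.
#'
#' @param gm a [genotype_matrix()].
#' @param breed_map named character vector from [read_breed_map()].
#' @return the genotype matrix with `breed_of` set.
#' @export
attach_breeds <- function(gm, breed_map) {
  miss <- setdiff(gm$samples, names(breed_map))
  if (length(miss) > 0)
    stop("samples without breed: ", paste(miss, collapse = ", "))
  gm$breed_of <- breed_map[gm$samples]
  gm
}

#' Write / read a frequency table
#'
#' Tab-separated, row labels in the first column, numeric cells rendered
#' with 6 decimals so that write/read round-trips are stable to 1e-6.
#'
#' @param tab numeric matrix with row and column names.
#' @param path file path.
#' @return `path` (write) or a numeric matrix (read).
#' @export
write_frequency_table <- function(tab, path) {
  df <- as.data.frame(formatC(tab, format = "f", digits = 6))
  df <- cbind(label = rownames(tab), df)
  write_tsv(df, path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a dendrogram as Newick
#'
#' @param tree an `upgma` tree from [average_linkage()], or an `hclust`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ph <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(ph, file = path)
  invisible(path)
}
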