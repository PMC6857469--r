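#' Configuration for the synthetic multi-breed cohort generator
#'
#' The generator stands in for the access-restricted multi-breed
#' whole-genome sequencing panel. Its defaults are the published study
#' conditions: the 14 breeds with their sample sizes, per-breed four-gene
#' protein-haplotype frequencies from the published haplotype table
#' (Residual dropped and columns renormalized), and filler SNP counts per
#' consequence category matching the published 892-SNP category breakdown
#' (87.3\% intron etc.).
#'
#' @param breeds named integer vector, animals per breed (>= 1 each).
#' @param haplotype_freqs named list breed -> named numeric vector of
#'   four-gene haplotype frequencies (labels like "B-A1-A-A"); renormalized
#'   to sum to 1. Defaults to [breed_haplotype_freqs()] per breed.
#' @param mean_depth expected sequencing reads per chromosome copy at a
#'   site (Poisson mean per allele copy); default 5, i.e. ~10x total.
#' @param missing_rate fraction of genotypes masked to missing, in [0,1).
#' @param category_counts named integer vector of filler SNP counts per
#'   consequence category; the seven defining missense SNPs count towards
#'   the `missense` entry.
#' @param upstream_length upstream window size in bp.
#' @param seed integer seed driving all randomness.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(breeds = breed_sample_sizes(),
                       haplotype_freqs = NULL,
                       mean_depth = 5,
                       missing_rate = 0.02,
                       category_counts = default_category_counts(),
                       upstream_length = 1000,
                       seed = 1) {
  stopifnot(length(breeds) >= 1, all(breeds >= 1), !is.null(names(breeds)))
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
  if (any(category_counts < 0)) stop("category counts must be non-negative")
  if (is.null(haplotype_freqs))
    haplotype_freqs <- lapply(stats::setNames(names(breeds), names(breeds)),
                              breed_haplotype_freqs)
  haplotype_freqs <- lapply(haplotype_freqs, function(p) {
    if (any(p < 0) || sum(p) <= 0) stop("invalid haplotype frequencies")
    p / sum(p)
  })
  if (!setequal(names(haplotype_freqs), names(breeds)))
    stop("haplotype_freqs must cover exactly the configured breeds")
  structure(list(breeds = breeds, haplotype_freqs = haplotype_freqs,
                 mean_depth = mean_depth, missing_rate = missing_rate,
                 category_counts = category_counts,
                 upstream_length = upstream_length, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default filler SNP counts per consequence category
#'
#' Matches the published 892-SNP breakdown over the cluster: 87.3\% intron,
#' 5.8\% upstream, 2.2\% missense, 2.2\% 3'-UTR, 1.2\% synonymous, 0.7\%
#' splice region, 0.4\% 5'-UTR.
#'
#' @return named integer vector summing to 892.
#' @export
default_category_counts <- function() {
  c(upstream = 52L, utr5 = 4L, intron = 779L, splice_region = 6L,
    synonymous = 11L, missense = 20L, utr3 = 20L)
}

# Genomic alleles carried by each named per-gene protein variant at the
# seven defining SNP positions (genomic order within gene). Protein
# variants distinguished only at the protein level or at unsequenced sites
# collapse onto the allele pattern of their background variant (B/F onto
# A1; C/D of CSN1S2 onto A; C of CSN1S1 is the alternative allele).
VARIANT_ALLELES <- list(
  CSN1S1 = list(pos = 87157262,
                B = "A", C = "G"),
  CSN2   = list(pos = c(87181542, 87181619),
                A1 = c("T", "T"), A2 = c("T", "G"), I = c("G", "G"),
                B = c("T", "T"), F = c("T", "T")),
  CSN1S2 = list(pos = 87266177,
                A = "C", C = "C", D = "C"),
  CSN3   = list(pos = c(87390576, 87390612, 87390632),
                A = c("C", "C", "A"), B = c("T", "A", "A"),
                E = c("C", "C", "G"))
)

#' Expand a four-gene haplotype label to SNP alleles
#'
#' Maps a comprehensive haplotype label (gene order CSN1S1-CSN2-CSN1S2-CSN3,
#' e.g. "B-A1-A-A") to the genomic alleles it carries at the seven defining
#' missense SNPs. Variants that are indistinguishable at these SNPs (e.g.
#' CSN2*B, which shares the His67 allele with A1) map to their background
#' pattern.
#'
#' @param label haplotype label string.
#' @return named character vector of alleles, names = positions (sorted).
#' @export
hap_label_alleles <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  if (length(parts) != 4) stop("unknown haplotype label: ", label)
  genes <- names(VARIANT_ALLELES)
  out <- c()
  for (i in seq_along(genes)) {
    va <- VARIANT_ALLELES[[genes[i]]]
    if (!parts[i] %in% names(va))
      stop("unknown haplotype label: ", label, " (", genes[i], "*", parts[i], ")")
    out <- c(out, stats::setNames(va[[parts[i]]], va$pos))
  }
  out[order(as.integer(names(out)))]
}

# --- filler SNP placement ---------------------------------------------------

# candidate genomic positions per category, given the gene models
category_pools <- function(models) {
  pools <- list(upstream = integer(0), utr5 = integer(0), utr3 = integer(0),
                intron = integer(0), splice_region = integer(0),
                coding = integer(0))
  expand <- function(iv) if (nrow(iv) == 0) integer(0) else
    unlist(lapply(seq_len(nrow(iv)), function(i) iv[i, 1]:iv[i, 2]))
  for (gm in models) {
    pools$upstream <- c(pools$upstream, gm$upstream[1]:gm$upstream[2])
    pools$utr5 <- c(pools$utr5, expand(gm$utr5))
    pools$utr3 <- c(pools$utr3, expand(gm$utr3))
    intr <- introns_of(gm)
    ipos <- expand(intr)
    spl <- integer(0)
    if (nrow(intr) > 0) {
      for (i in seq_len(nrow(intr))) {
        s <- intr[i, 1]; e <- intr[i, 2]
        spl <- c(spl, s:(s + 7), (e - 7):e,      # intronic 1-8
                 (s - 3):(s - 1), (e + 1):(e + 3)) # exonic 1-3
      }
    }
    pools$splice_region <- c(pools$splice_region, spl)
    pools$intron <- c(pools$intron, setdiff(ipos, spl))
    # coding positions away from splice regions and from start/stop codons
    cod <- gm$cds_map[4:(length(gm$cds_map) - 3)]
    pools$coding <- c(pools$coding, setdiff(cod, spl))
  }
  pools
}

# choose a filler substitution at a coding position; returns c(ref, alt) or
# NULL if the position cannot yield the requested class
coding_filler_alleles <- function(pos, gm, ref, synonymous) {
  cpos <- coding_position(gm, pos)
  codon_idx <- (cpos - 1) %/% 3 + 1
  k <- (cpos - 1) %% 3 + 1
  gpos <- genomic_position(gm, (codon_idx - 1) * 3 + 1:3)
  codon <- reference_base(ref, gpos)
  if (gm$strand == "-") codon <- complement(codon)
  ref_aa <- CODON_TABLE[paste(codon, collapse = "")]
  if (ref_aa == "*") return(NULL)
  for (b in sample(setdiff(c("A", "C", "G", "T"), codon[k]))) {
    cod2 <- codon; cod2[k] <- b
    aa2 <- CODON_TABLE[paste(cod2, collapse = "")]
    ok <- if (synonymous) aa2 == ref_aa else (aa2 != ref_aa && aa2 != "*")
    if (ok) {
      alt <- if (gm$strand == "+") b else complement(b)
      return(c(reference_base(ref, pos), alt))
    }
  }
  NULL
}

# place filler SNPs; returns data.frame(pos, ref, alt, category, gene)
place_filler_snps <- function(models, ref, category_counts, reserved) {
  pools <- category_pools(models)
  gene_of <- function(pos) {
    for (gm in models)
      if ((pos >= gm$tx[1] && pos <= gm$tx[2]) ||
          (pos >= gm$upstream[1] && pos <= gm$upstream[2])) return(gm$gene_id)
    NA_character_
  }
  res <- list()
  noncoding <- c("upstream", "utr5", "utr3", "intron", "splice_region")
  for (cat in names(category_counts)) {
    n <- category_counts[[cat]]
    if (n == 0) next
    if (cat %in% noncoding) {
      pool <- setdiff(pools[[cat]], reserved)
      if (length(pool) < n)
        stop("category count for ", cat, " exceeds available region length")
      pos <- sort(sample(pool, n))
      rb <- reference_base(ref, pos)
      alt <- vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1))
      res[[cat]] <- data.frame(pos = pos, ref = rb, alt = unname(alt),
                               category = cat, stringsAsFactors = FALSE)
    } else if (cat %in% c("synonymous", "missense")) {
      n_needed <- if (cat == "missense") n - length(reserved_missense(reserved)) else n
      if (n_needed < 0) stop("missense count below the 7 defining SNPs")
      pool <- setdiff(pools$coding, reserved)
      picked <- integer(0); refs <- character(0); alts <- character(0)
      pool <- sample(pool)
      i <- 1
      while (length(picked) < n_needed && i <= length(pool)) {
        p <- pool[i]; i <- i + 1
        gm <- models[[gene_of(p)]]
        al <- coding_filler_alleles(p, gm, ref, synonymous = cat == "synonymous")
        if (!is.null(al)) {
          picked <- c(picked, p); refs <- c(refs, al[1]); alts <- c(alts, al[2])
          # avoid stacking two fillers in one codon
          cpos <- coding_position(gm, p)
          ci <- (cpos - 1) %/% 3 + 1
          pool <- setdiff(pool, genomic_position(gm, (ci - 1) * 3 + 1:3))
        }
      }
      if (length(picked) < n_needed)
        stop("category count for ", cat, " exceeds available region length")
      o <- order(picked)
      res[[cat]] <- data.frame(pos = picked[o], ref = refs[o], alt = alts[o],
                               category = cat, stringsAsFactors = FALSE)
    } else stop("unknown category: ", cat)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(pos = integer(0), ref = character(0),
                                      alt = character(0), category = character(0))
  out$gene <- vapply(out$pos, gene_of, character(1))
  rownames(out) <- NULL
  out
}

reserved_missense <- function(reserved) reserved  # the 7 defining SNPs

# --- cohort simulation ------------------------------------------------------

#' Simulate a multi-breed sequencing cohort
#'
#' For each animal two four-gene haplotypes are drawn i.i.d. from its
#' breed's haplotype distribution and expanded to genomic alleles at the
#' seven defining missense SNPs. Filler SNPs are placed per category with
#' a site-specific alternative allele frequency drawn uniformly from
#' [0.05, 0.95] and Hardy-Weinberg genotypes i.i.d. across animals. Allele
#' depths are Poisson(`mean_depth`) per chromosome copy; genotypes are
#' masked to missing at `missing_rate`. Writes VCF 4.2 (GT, AD), GFF3,
#' FASTA, a breed map TSV and a truth TSV.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return object of class `fixture_bundle`: paths, gene models, reference,
#'   variant table with true categories, truth haplotypes and the config.
#' @export
simulate_cohort <- function(config, dir = tempfile("casein_fixture_")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- build_gene_models(config$upstream_length)
  ref <- build_reference(models, seed = config$seed)

  snp_tab <- casein_snp_table()
  core <- unique(snp_tab[, c("gene", "pos", "ref", "alt", "snp_id")])
  core <- core[order(core$pos), ]
  core_pos <- core$pos

  out <- with_seed(config$seed + 1L, {
    fillers <- place_filler_snps(models, ref, config$category_counts,
                                 reserved = core_pos)
    fillers$id <- rep(".", nrow(fillers))
    variants <- rbind(
      data.frame(pos = core$pos, ref = core$ref, alt = core$alt,
                 category = "missense", gene = core$gene,
                 id = core$snp_id, stringsAsFactors = FALSE),
      fillers)
    variants <- variants[order(variants$pos), ]
    rownames(variants) <- NULL

    samples <- unlist(lapply(names(config$breeds), function(b) {
      sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", b),
              seq_len(config$breeds[[b]]))
    }))
    breed_of <- stats::setNames(rep(names(config$breeds), config$breeds), samples)
    n <- length(samples)

    # haplotype truth: two labels per animal
    labs1 <- character(n); labs2 <- character(n)
    i0 <- 0
    for (b in names(config$breeds)) {
      nb <- config$breeds[[b]]
      p <- config$haplotype_freqs[[b]]
      draw <- sample(names(p), 2 * nb, replace = TRUE, prob = p)
      labs1[i0 + seq_len(nb)] <- draw[seq_len(nb)]
      labs2[i0 + seq_len(nb)] <- draw[nb + seq_len(nb)]
      i0 <- i0 + nb
    }
    hap_alleles <- vapply(sort(unique(c(labs1, labs2))), hap_label_alleles,
                          character(length(core_pos)))
    # dosage at core SNPs: count of alternative alleles
    alt_of <- stats::setNames(core$alt, as.character(core$pos))
    core_dos <- matrix(0L, n, length(core_pos))
    for (j in seq_along(core_pos)) {
      pj <- as.character(core_pos[j])
      a1 <- hap_alleles[pj, labs1]
      a2 <- hap_alleles[pj, labs2]
      core_dos[, j] <- (a1 == alt_of[[pj]]) + (a2 == alt_of[[pj]])
    }

    # filler dosages: HWE at a site-specific global AAF
    nf <- nrow(variants) - length(core_pos)
    filler_rows <- which(!(variants$pos %in% core_pos))
    aaf <- stats::runif(nf, 0.05, 0.95)
    dosage <- matrix(0L, n, nrow(variants))
    dosage[, match(core_pos, variants$pos)] <- core_dos
    for (k in seq_along(filler_rows))
      dosage[, filler_rows[k]] <- stats::rbinom(n, 2, aaf[k])

    # allele depths: Poisson per chromosome copy
    nv <- nrow(variants)
    r1 <- matrix(stats::rpois(n * nv, config$mean_depth), n, nv)
    r2 <- matrix(stats::rpois(n * nv, config$mean_depth), n, nv)
    ad_ref <- (dosage == 0) * (r1 + r2) + (dosage == 1) * r1
    ad_alt <- (dosage == 2) * (r1 + r2) + (dosage == 1) * r2
    miss <- matrix(stats::runif(n * nv) < config$missing_rate, n, nv)
    dosage[miss] <- NA_integer_

    list(variants = variants, samples = samples, breed_of = breed_of,
         dosage = dosage, ad_ref = ad_ref, ad_alt = ad_alt,
         truth = data.frame(sample_id = samples, hap1 = labs1, hap2 = labs2,
                            stringsAsFactors = FALSE))
  })

  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                breed_map = file.path(dir, "breeds.tsv"),
                truth = file.path(dir, "truth.tsv"),
                gff3 = file.path(dir, "genes.gff3"),
                fasta = file.path(dir, "reference.fa"))
  write_vcf(out$variants, out$samples, out$dosage, out$ad_ref, out$ad_alt,
            chrom = ref$chrom, path = paths$vcf)
  write_tsv(data.frame(sample_id = out$samples,
                       breed = unname(out$breed_of[out$samples])),
            paths$breed_map)
  write_tsv(out$truth, paths$truth)
  write_gff3(models, paths$gff3)
  write_reference_fasta(ref, paths$fasta)

  structure(list(dir = dir, paths = paths, models = models, reference = ref,
                 variants = out$variants, truth = out$truth,
                 breed_of = out$breed_of, config = config),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d samples, %d SNPs, %d breeds in %s\n",
              nrow(x$truth), nrow(x$variants),
              length(unique(x$breed_of)), x$dir))
  invisible(x)
}
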