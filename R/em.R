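#' Haplotype frequency estimation from unphased genotypes
#'
#' Gene-counting expectation-maximisation (Excoffier-Slatkin) over
#' multilocus SNP genotypes: the E-step distributes each individual over
#' the haplotype pairs compatible with its dosages in proportion to
#' c * p_h * p_k (c = 2 for heterozygous pairs), the M-step re-estimates
#' frequencies from expected haplotype counts. The log-likelihood is
#' non-decreasing and iteration stops when its change falls below `tol`.
#' Runs are bit-reproducible: initialisation is uniform over compatible
#' haplotypes and haplotypes are ordered lexicographically.
#'
#' @name haplotype-em
NULL

#' Enumerate haplotype pairs compatible with a multilocus genotype
#'
#' Haplotypes are encoded as strings over \{0,1\} (0 = reference allele).
#' Heterozygous loci contribute a factor 2 of ordered assignments, missing
#' loci leave both haplotypes free. Unordered pairs are returned, so a
#' genotype with k heterozygous loci and no missing data yields
#' 2^(k-1) pairs.
#'
#' @param dosage integer vector over loci in \{0,1,2,NA\}.
#' @param max_ambiguity cap on the number of unresolved (heterozygous or
#'   missing) loci; exceeding it is an error (callers exclude the
#'   individual with a warning).
#' @return character matrix with columns `h1`, `h2` (h1 <= h2).
#' @export
enumerate_pairs <- function(dosage, max_ambiguity = 12) {
  L <- length(dosage)
  het <- which(!is.na(dosage) & dosage == 1)
  mis <- which(is.na(dosage))
  if (length(het) + length(mis) > max_ambiguity)
    stop("ambiguity cap exceeded: ", length(het) + length(mis),
         " unresolved loci > ", max_ambiguity)
  base <- ifelse(is.na(dosage), 0L, ifelse(dosage == 2, 1L, 0L))
  h1 <- matrix(base, nrow = 1)
  h2 <- h1
  expand <- function(h1, h2, choices) {
    # choices: list of (a1, a2) allele assignments for one locus
    n <- nrow(h1)
    h1 <- h1[rep(seq_len(n), times = length(choices)), , drop = FALSE]
    h2 <- h2[rep(seq_len(n), times = length(choices)), , drop = FALSE]
    list(h1 = h1, h2 = h2,
         idx = rep(seq_along(choices), each = n))
  }
  for (l in het) {
    e <- expand(h1, h2, list(c(0L, 1L), c(1L, 0L)))
    a <- do.call(rbind, list(c(0L, 1L), c(1L, 0L)))[e$idx, , drop = FALSE]
    h1 <- e$h1; h2 <- e$h2
    h1[, l] <- a[, 1]; h2[, l] <- a[, 2]
  }
  for (l in mis) {
    ch <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
    e <- expand(h1, h2, ch)
    a <- do.call(rbind, ch)[e$idx, , drop = FALSE]
    h1 <- e$h1; h2 <- e$h2
    h1[, l] <- a[, 1]; h2[, l] <- a[, 2]
  }
  s1 <- apply(h1, 1, paste, collapse = "")
  s2 <- apply(h2, 1, paste, collapse = "")
  lo <- pmin(s1, s2); hi <- pmax(s1, s2)
  keep <- !duplicated(paste(lo, hi))
  cbind(h1 = lo[keep], h2 = hi[keep])
}

#' Fit haplotype frequencies by EM
#'
#' @param genotypes integer matrix individuals x loci, dosages in
#'   \{0,1,2,NA\}.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @param max_ambiguity per-individual cap passed to [enumerate_pairs()];
#'   individuals above the cap, or missing more than half of the block's
#'   loci, are excluded with a warning.
#' @param alleles optional list(ref=, alt=) of allele characters per locus
#'   used to express haplotypes as allele strings.
#' @return object of class `em_result`: `haplotypes` (0/1 strings),
#'   `allele_strings` (if alleles given), `freqs`, `loglik` (trace),
#'   `n_iter`, `converged`, `n_used`, `excluded`, `posterior` (per kept
#'   individual, data.frame of pairs and weights).
#' @export
em_fit <- function(genotypes, tol = 1e-8, max_iter = 1000,
                   max_ambiguity = 12, alleles = NULL) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  n <- nrow(genotypes); L <- ncol(genotypes)
  unresolved <- rowSums(genotypes == 1, na.rm = TRUE) + rowSums(is.na(genotypes))
  too_missing <- rowSums(is.na(genotypes)) > L / 2
  drop <- unresolved > max_ambiguity | too_missing
  if (any(drop))
    warning(sum(drop), " individual(s) excluded (ambiguity cap or >50% missing)")
  excluded <- which(drop)
  genotypes <- genotypes[!drop, , drop = FALSE]
  if (nrow(genotypes) == 0) stop("no individuals left after ambiguity cap")

  key <- apply(genotypes, 1, function(g) paste(ifelse(is.na(g), ".", g),
                                               collapse = ""))
  patt <- !duplicated(key)
  pat_key <- key[patt]
  weight <- as.vector(table(factor(key, levels = pat_key)))
  pat_geno <- genotypes[patt, , drop = FALSE]

  pairs <- lapply(seq_len(nrow(pat_geno)), function(i)
    enumerate_pairs(pat_geno[i, ], max_ambiguity))
  haps <- sort(unique(unlist(pairs)))
  H <- length(haps)
  pair_idx <- lapply(pairs, function(pm)
    cbind(i1 = match(pm[, 1], haps), i2 = match(pm[, 2], haps)))
  if (any(vapply(pair_idx, nrow, integer(1)) == 0))
    stop("contradictory genotype: no compatible haplotype pair")

  p <- rep(1 / H, H)
  ll_trace <- numeric(0)
  converged <- FALSE
  N2 <- 2 * sum(weight)
  for (iter in seq_len(max_iter)) {
    ll <- 0
    counts <- numeric(H)
    for (j in seq_along(pair_idx)) {
      pi <- pair_idx[[j]]
      cc <- ifelse(pi[, 1] == pi[, 2], 1, 2)
      num <- cc * p[pi[, 1]] * p[pi[, 2]]
      tot <- sum(num)
      ll <- ll + weight[j] * log(tot)
      w <- num / tot
      add <- weight[j] * w
      # accumulate with possibly repeated haplotype indices
      acc <- rowsum(c(add, add), c(pi[, 1], pi[, 2]))
      counts[as.integer(rownames(acc))] <-
        counts[as.integer(rownames(acc))] + acc[, 1]
    }
    # counts sums pair members; each pair contributes 2 haplotypes
    p_new <- counts / N2
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 && abs(ll - ll_trace[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
    p <- p_new
  }
  names(p) <- haps
  posterior <- lapply(seq_along(pair_idx), function(j) {
    pi <- pair_idx[[j]]
    cc <- ifelse(pi[, 1] == pi[, 2], 1, 2)
    num <- cc * p[pi[, 1]] * p[pi[, 2]]
    data.frame(h1 = haps[pi[, 1]], h2 = haps[pi[, 2]],
               weight = num / sum(num), stringsAsFactors = FALSE)
  })
  names(posterior) <- pat_key
  res <- list(haplotypes = haps, freqs = p, loglik = ll_trace,
              n_iter = length(ll_trace), converged = converged,
              n_used = sum(weight), excluded = excluded,
              pattern_of = key, posterior = posterior)
  if (!is.null(alleles)) {
    decode <- function(h) {
      bits <- as.integer(strsplit(h, "")[[1]])
      paste(ifelse(bits == 1, alleles$alt, alleles$ref), collapse = "")
    }
    res$allele_strings <- stats::setNames(vapply(haps, decode, character(1)),
                                          haps)
  }
  structure(res, class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("<em_result> %d haplotypes, n=%d, %d iteration(s), %s\n",
              length(x$freqs), x$n_used, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  top <- sort(x$freqs, decreasing = TRUE)
  top <- top[top > 0.001]
  lab <- if (!is.null(x$allele_strings)) x$allele_strings[names(top)] else names(top)
  for (i in seq_along(top))
    cat(sprintf("  %s  %.4f\n", lab[i], top[i]))
  invisible(x)
}

#' Per-breed and pooled EM fits over a locus block
#'
#' @param gm a [genotype_matrix()] with breeds attached.
#' @param positions loci of the block (genomic positions present in
#'   `gm$variants$pos`).
#' @param ... passed to [em_fit()].
#' @return list with `breeds` (named list of `em_result`), `pooled`
#'   (`em_result` over all animals) and `positions`.
#' @export
per_breed_frequencies <- function(gm, positions, ...) {
  j <- match(positions, gm$variants$pos)
  if (anyNA(j)) stop("block positions absent from the genotype matrix: ",
                     paste(positions[is.na(j)], collapse = ", "))
  if (is.null(gm$breed_of)) stop("breed map not attached")
  alleles <- list(ref = gm$variants$ref[j], alt = gm$variants$alt[j])
  sub <- gm$dosage[, j, drop = FALSE]
  br <- gm$breed_of[gm$samples]
  fits <- lapply(split(seq_along(br), br), function(rows) {
    if (length(rows) == 0) stop("breed with zero callable individuals")
    em_fit(sub[rows, , drop = FALSE], alleles = alleles, ...)
  })
  pooled <- em_fit(sub, alleles = alleles, ...)
  list(breeds = fits, pooled = pooled, positions = positions,
       alleles = alleles)
}

#' Assemble the comprehensive four-gene haplotype frequency table
#'
#' Maps each estimated SNP haplotype over the seven defining missense SNPs
#' to a four-gene protein haplotype label via the protein-variant rules,
#' then applies the published inclusion rules: protein variants that do
#' not reach `min_variant_freq` in any single breed are excluded (their
#' haplotypes move to Residual), and named haplotypes that stay below
#' `residual_threshold` in every breed are pooled into Residual.
#'
#' @param fits result of [per_breed_frequencies()] over the 7-SNP block.
#' @param rules protein-variant rules, see [builtin_rules()].
#' @param min_variant_freq per-breed inclusion threshold for protein
#'   variants (default 0.05).
#' @param residual_threshold pooling threshold for named haplotypes
#'   (default 0.05).
#' @return numeric matrix, haplotype labels + "Residual" x
#'   c("Total", breeds); attribute `n_animals` carries per-column counts.
#' @export
comprehensive_haplotypes <- function(fits, rules = builtin_rules(),
                                     min_variant_freq = 0.05,
                                     residual_threshold = 0.05) {
  positions <- fits$positions
  label_of_hap <- function(allele_string) {
    al <- stats::setNames(strsplit(allele_string, "")[[1]],
                          as.character(positions))
    parts <- vapply(unique(rules$gene), function(g)
      call_variant(al, rules, g), character(1))
    if (any(parts == "unassigned")) return(NA_character_)
    paste(parts, collapse = "-")
  }
  cols <- c("Total", names(fits$breeds))
  freq_of <- function(fit) {
    labs <- vapply(unname(fit$allele_strings[fit$haplotypes]), label_of_hap,
                   character(1))
    tapply(fit$freqs, factor(ifelse(is.na(labs), "Residual", labs)), sum)
  }
  per_col <- c(list(Total = freq_of(fits$pooled)),
               lapply(fits$breeds, freq_of))
  labels <- union(sort(unique(unlist(lapply(per_col, names)))), "Residual")
  tab <- matrix(0, length(labels), length(cols),
                dimnames = list(labels, cols))
  for (cn in cols) tab[names(per_col[[cn]]), cn] <- per_col[[cn]]

  # per-gene protein variant frequencies per breed, for the inclusion rule
  named <- setdiff(rownames(tab), "Residual")
  breeds_only <- setdiff(cols, "Total")
  genes <- unique(rules$gene)
  drop_variant <- character(0)
  for (gi in seq_along(genes)) {
    parts <- vapply(strsplit(named, "-"), `[`, character(1), gi)
    for (v in unique(parts)) {
      vf <- vapply(breeds_only, function(b) sum(tab[named, b][parts == v]),
                   numeric(1))
      if (max(vf) < min_variant_freq)
        drop_variant <- c(drop_variant, paste0(genes[gi], "*", v))
    }
  }
  if (length(drop_variant) > 0) {
    hit <- vapply(strsplit(named, "-"), function(pp)
      any(paste0(genes, "*", pp) %in% drop_variant), logical(1))
    tab["Residual", ] <- tab["Residual", ] + colSums(tab[named[hit], , drop = FALSE])
    tab <- tab[!(rownames(tab) %in% named[hit]), , drop = FALSE]
    named <- named[!hit]
  }
  # pool rare named haplotypes
  rare <- vapply(named, function(h)
    max(tab[h, breeds_only]) < residual_threshold, logical(1))
  if (any(rare)) {
    tab["Residual", ] <- tab["Residual", ] + colSums(tab[named[rare], , drop = FALSE])
    tab <- tab[!(rownames(tab) %in% named[rare]), , drop = FALSE]
  }
  named <- setdiff(rownames(tab), "Residual")
  tab <- tab[c(named[order(-tab[named, "Total"])], "Residual"), , drop = FALSE]
  attr(tab, "n_animals") <- c(Total = fits$pooled$n_used,
                              vapply(fits$breeds, function(f) f$n_used,
                                     integer(1)))
  tab
}

#' Theoretically possible haplotype count for one breed
#'
#' Product over genes of the number of protein variants detected (nonzero
#' frequency) in the breed.
#'
#' @param freqs data.frame from [variant_frequencies()] (columns gene,
#'   variant, breed, freq).
#' @param breed breed name.
#' @return integer.
#' @export
theoretical_haplotype_count <- function(freqs, breed) {
  f <- freqs[freqs$breed == breed & freqs$variant != "unassigned" &
               freqs$freq > 0, ]
  prod(vapply(split(f, f$gene), nrow, integer(1)))
}
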