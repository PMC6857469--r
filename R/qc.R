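#' Data-cleaning filters for multi-breed genotype panels
#'
#' The cleaning pipeline applies, in this fixed order: (1) read-depth
#' genotype trust (a called genotype needs at least `min_reads` reads over
#' the two alleles, else it is set to missing); (2) removal of animals
#' sharing suspiciously high genetic similarity (> 0.99 relative Manhattan
#' similarity), keeping one member per pair; (3) a breed-size floor
#' (breeds with fewer than 30 animals are dropped); (4) removal of
#' variants that are monomorphic in every remaining breed. The order is
#' idempotent: re-running on filtered output changes nothing.
#'
#' @name qc-filters
NULL

new_filter_report <- function() {
  structure(list(genotypes_masked = 0L,
                 animals_removed = data.frame(sample = character(0),
                                              reason = character(0),
                                              stringsAsFactors = FALSE),
                 variants_removed = 0L,
                 breeds_kept = character(0),
                 notes = character(0)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> %d genotype(s) masked, %d animal(s) ",
                     "removed, %d variant(s) removed, %d breed(s) kept\n"),
              x$genotypes_masked, nrow(x$animals_removed),
              x$variants_removed, length(x$breeds_kept)))
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# caseinhap filter report",
               "# similarity is 1 - Manhattan distance / (2 * shared loci); removal keeps the member with fewer missing genotypes (assumption)",
               paste0("genotypes_masked\t", report$genotypes_masked),
               paste0("variants_removed\t", report$variants_removed),
               paste0("breeds_kept\t", paste(report$breeds_kept, collapse = ","))),
             con)
  if (nrow(report$animals_removed) > 0)
    writeLines(paste0("animal_removed\t", report$animals_removed$sample,
                      "\t", report$animals_removed$reason), con)
  invisible(path)
}

#' Depth-based genotype trust filter
#'
#' Sets a genotype to missing when fewer than `min_reads` reads map to the
#' reference plus alternative allele. Genotypes with unknown depth are
#' kept and counted in the report notes.
#'
#' @param gm a [genotype_matrix()].
#' @param min_reads minimum total reads (default 3).
#' @return the filtered genotype matrix, with a `filter_report` attribute.
#' @export
depth_trust_filter <- function(gm, min_reads = 3) {
  if (min_reads < 1) stop("min_reads must be >= 1")
  rep <- new_filter_report()
  if (is.null(gm$ad_ref)) {
    rep$notes <- "no allele depths available; depth filter skipped"
  } else {
    tot <- gm$ad_ref + gm$ad_alt
    unknown <- is.na(tot)
    mask <- !unknown & tot < min_reads & !is.na(gm$dosage)
    gm$dosage[mask] <- NA_integer_
    rep$genotypes_masked <- sum(mask)
    if (any(unknown))
      rep$notes <- sprintf("%d genotype(s) with unknown depth kept", sum(unknown))
  }
  attr(gm, "filter_report") <- rep
  gm
}

#' Pairwise relative Manhattan similarity between samples
#'
#' For samples i, j over the variants called in both,
#' s(i,j) = 1 - sum |d_i - d_j| / (2 L), with L the number of shared
#' called variants; s is in [0,1], 1 on the diagonal. Pairs with no shared
#' called variant are NA.
#'
#' @param gm a [genotype_matrix()] (>= 2 samples).
#' @return symmetric numeric matrix samples x samples.
#' @export
relative_manhattan_similarity <- function(gm) {
  d <- gm$dosage
  if (nrow(d) < 2) stop("need at least two samples")
  called <- !is.na(d)
  I0 <- called & d == 0; I1 <- called & d == 1; I2 <- called & d == 2
  I0[is.na(I0)] <- FALSE; I1[is.na(I1)] <- FALSE; I2[is.na(I2)] <- FALSE
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  M <- called; storage.mode(M) <- "double"
  L <- tcrossprod(M)
  manh <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  s <- 1 - manh / (2 * L)
  s[L == 0] <- NA_real_
  diag(s) <- 1
  dimnames(s) <- list(gm$samples, gm$samples)
  s
}

#' Remove near-duplicate animals
#'
#' Repeatedly removes one member of every sample pair whose similarity
#' exceeds `threshold`, preferring to drop the member with more missing
#' genotypes (ties broken towards the lexicographically larger id), until
#' no pair exceeds the threshold.
#'
#' @param gm a [genotype_matrix()].
#' @param threshold similarity threshold (default 0.99).
#' @return list(matrix = filtered [genotype_matrix()], report = `filter_report`).
#' @export
drop_similar_animals <- function(gm, threshold = 0.99) {
  rep <- new_filter_report()
  repeat {
    s <- relative_manhattan_similarity(gm)
    s[lower.tri(s, diag = TRUE)] <- NA
    hit <- which(!is.na(s) & s > threshold, arr.ind = TRUE)
    if (nrow(hit) == 0) break
    i <- hit[1, 1]; j <- hit[1, 2]
    a <- gm$samples[i]; b <- gm$samples[j]
    miss <- rowSums(is.na(gm$dosage[c(i, j), , drop = FALSE]))
    drop <- if (miss[1] > miss[2]) a
            else if (miss[2] > miss[1]) b
            else max(a, b)
    rep$animals_removed <- rbind(rep$animals_removed,
      data.frame(sample = drop,
                 reason = sprintf("similarity %.4f with %s > %.2f",
                                  s[i, j], setdiff(c(a, b), drop), threshold),
                 stringsAsFactors = FALSE))
    keep <- gm$samples != drop
    gm <- subset_samples(gm, keep)
  }
  attr(gm, "filter_report") <- rep
  list(matrix = gm, report = rep)
}

subset_samples <- function(gm, keep) {
  genotype_matrix(gm$samples[keep], gm$variants,
                  gm$dosage[keep, , drop = FALSE],
                  if (is.null(gm$ad_ref)) NULL else gm$ad_ref[keep, , drop = FALSE],
                  if (is.null(gm$ad_alt)) NULL else gm$ad_alt[keep, , drop = FALSE],
                  gm$breed_of)
}

subset_variants <- function(gm, keep) {
  genotype_matrix(gm$samples, gm$variants[keep, , drop = FALSE],
                  gm$dosage[, keep, drop = FALSE],
                  if (is.null(gm$ad_ref)) NULL else gm$ad_ref[, keep, drop = FALSE],
                  if (is.null(gm$ad_alt)) NULL else gm$ad_alt[, keep, drop = FALSE],
                  gm$breed_of)
}

#' Breed-size floor and polymorphism filter
#'
#' Drops breeds with fewer than `min_breed_size` animals together with
#' their samples, then drops variants that are monomorphic (no called
#' heterozygote or alternative homozygote, or fixed alternative) in every
#' remaining breed.
#'
#' @param gm a [genotype_matrix()] with breeds attached.
#' @param min_breed_size minimum animals per breed (default 30).
#' @return list(matrix, report) as in [drop_similar_animals()].
#' @export
breed_polymorphism_filter <- function(gm, min_breed_size = 30) {
  if (is.null(gm$breed_of)) stop("breed map not attached")
  rep <- new_filter_report()
  sizes <- table(gm$breed_of[gm$samples])
  keep_breeds <- names(sizes)[sizes >= min_breed_size]
  if (length(keep_breeds) == 0) stop("no breed reaches the size floor of ",
                                     min_breed_size)
  drop_samples <- gm$samples[!(gm$breed_of[gm$samples] %in% keep_breeds)]
  if (length(drop_samples) > 0) {
    rep$animals_removed <- data.frame(
      sample = drop_samples,
      reason = sprintf("breed %s below size floor %d",
                       gm$breed_of[drop_samples], min_breed_size),
      stringsAsFactors = FALSE)
    gm <- subset_samples(gm, !(gm$samples %in% drop_samples))
  }
  rep$breeds_kept <- sort(keep_breeds)
  # polymorphic in at least one breed: within some breed, both alleles seen
  br <- gm$breed_of[gm$samples]
  poly <- rep(FALSE, nrow(gm$variants))
  for (b in keep_breeds) {
    d <- gm$dosage[br == b, , drop = FALSE]
    alt_seen <- colSums(d > 0, na.rm = TRUE) > 0
    ref_seen <- colSums(d < 2, na.rm = TRUE) > 0
    poly <- poly | (alt_seen & ref_seen)
  }
  rep$variants_removed <- sum(!poly)
  gm <- subset_variants(gm, poly)
  attr(gm, "filter_report") <- rep
  list(matrix = gm, report = rep)
}

#' Run the full cleaning pipeline in the fixed order
#'
#' @param gm a [genotype_matrix()] with breeds attached.
#' @param min_reads,similarity_threshold,min_breed_size filter settings.
#' @return list(matrix, report) where report merges all stages.
#' @export
qc_pipeline <- function(gm, min_reads = 3, similarity_threshold = 0.99,
                        min_breed_size = 30) {
  gm1 <- depth_trust_filter(gm, min_reads)
  r1 <- attr(gm1, "filter_report")
  s2 <- drop_similar_animals(gm1, similarity_threshold)
  s3 <- breed_polymorphism_filter(s2$matrix, min_breed_size)
  rep <- new_filter_report()
  rep$genotypes_masked <- r1$genotypes_masked
  rep$animals_removed <- rbind(s2$report$animals_removed,
                               s3$report$animals_removed)
  rep$variants_removed <- s3$report$variants_removed
  rep$breeds_kept <- s3$report$breeds_kept
  rep$notes <- c(r1$notes, s2$report$notes, s3$report$notes)
  list(matrix = s3$matrix, report = rep)
}
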