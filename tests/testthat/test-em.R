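test_that("pair enumeration counts follow 2^(k-1) and expands missing loci", {
  expect_equal(nrow(enumerate_pairs(c(0, 2, 0))), 1)  # fully homozygous
  expect_equal(nrow(enumerate_pairs(c(1, 1, 0))), 2)  # k = 2
  expect_equal(nrow(enumerate_pairs(c(1, 1, 1))), 4)  # k = 3
  # one missing locus: {0,1} x {0,1} unordered on top of a hom background
  pm <- enumerate_pairs(c(0, NA))
  expect_equal(nrow(pm), 3)  # 00/00, 00/01, 01/01
  expect_error(enumerate_pairs(rep(1, 13), max_ambiguity = 12), "ambiguity cap")
})

test_that("EM equals direct counting on unambiguous data", {
  # every individual has at most one heterozygous locus -> phase is known
  g <- rbind(c(0, 0), c(2, 2), c(1, 0), c(2, 1), c(0, 0))
  fit <- em_fit(g)
  haps <- c(`00` = 0, `01` = 0, `10` = 0, `11` = 0)
  for (i in seq_len(nrow(g))) {
    pm <- enumerate_pairs(g[i, ])
    haps[pm[1, 1]] <- haps[pm[1, 1]] + 1
    haps[pm[1, 2]] <- haps[pm[1, 2]] + 1
  }
  haps <- haps / sum(haps)
  expect_equal(fit$freqs[names(haps)[haps > 0]],
               haps[haps > 0], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("double heterozygote with uniform start sits at the symmetric fixed point", {
  fit <- em_fit(matrix(c(1, 1), 1, 2))
  expect_equal(unname(fit$freqs), rep(0.25, 4), tolerance = 1e-9)
  expect_setequal(fit$haplotypes, c("00", "01", "10", "11"))
})

test_that("log-likelihood is non-decreasing on random instances", {
  set.seed(20240601)
  for (rep in 1:10) {
    n <- sample(3:12, 1); L <- sample(2:5, 1)
    g <- matrix(sample(c(0L, 1L, 2L, NA), n * L, replace = TRUE,
                       prob = c(.35, .3, .3, .05)), n, L)
    g <- g[rowSums(!is.na(g)) > 0, , drop = FALSE]
    if (nrow(g) == 0) next
    fit <- suppressWarnings(em_fit(g))
    expect_true(all(diff(fit$loglik) > -1e-10))
    expect_equal(sum(fit$freqs), 1, tolerance = 1e-9)
    expect_true(all(fit$freqs >= 0))
  }
})

test_that("EM attains the simplex maximum found by 10,000 Dirichlet restarts (<=3 loci, <=6 individuals)", {
  set.seed(77)
  for (case in 1:3) {
    n <- sample(3:6, 1); L <- sample(2:3, 1)
    g <- matrix(sample(c(0L, 1L, 2L), n * L, replace = TRUE), n, L)
    fit <- em_fit(g)
    em_ll <- fit$loglik[length(fit$loglik)]
    # oracle: direct likelihood evaluation at 10,000 random simplex points
    # over ALL 2^L haplotypes, independent of the EM path
    expect_gte(em_ll, oracle_max_loglik(g, 10000) - 1e-6)
  }
})

test_that("EM marginal allele frequencies match dosage frequencies without missing data", {
  set.seed(5)
  g <- draw_dosage(breed_haplotype_freqs("DSN"), 60)
  fit <- em_fit(g)
  hb <- do.call(rbind, strsplit(fit$haplotypes, ""))
  em_af <- colSums((hb == "1") * fit$freqs)
  dos_af <- colMeans(g) / 2
  expect_equal(unname(em_af), unname(dos_af), tolerance = 1e-6)
})

test_that("parameter recovery at n = 5000 within 0.02", {
  set.seed(31)
  p <- breed_haplotype_freqs("DSN")
  g <- draw_dosage(p, 5000)
  core <- core_snps()
  fit <- em_fit(g, alleles = list(ref = core$ref, alt = core$alt))
  hapstr <- vapply(names(p), function(l)
    paste(hap_label_alleles(l), collapse = ""), character(1))
  est <- fit$freqs[match(hapstr, fit$allele_strings)]
  est[is.na(est)] <- 0
  expect_true(all(abs(est - p) < 0.02))
})

test_that("per-breed fits plus pooled fit behave like a mixture", {
  set.seed(8)
  fx <- simulate_cohort(sim_config(
    breeds = c(A = 40L, B = 40L),
    haplotype_freqs = list(A = c(`B-A1-A-A` = 1),
                           B = c(`B-A2-A-B` = 0.5, `B-A1-A-A` = 0.5)),
    category_counts = c(intron = 0L), missing_rate = 0, seed = 14))
  gm <- attach_breeds(read_vcf(fx$paths$vcf), read_breed_map(fx$paths$breed_map))
  fits <- per_breed_frequencies(gm, casein_snp_positions())
  # degenerate breed recovered exactly
  fA <- fits$breeds$A
  expect_equal(max(fA$freqs), 1, tolerance = 1e-6)
  expect_equal(unname(fA$allele_strings[names(which.max(fA$freqs))]),
               paste(hap_label_alleles("B-A1-A-A"), collapse = ""))
  # pooled = sample-size weighted mixture of the two breeds (exact here up
  # to sampling noise in breed B's draw)
  fP <- fits$pooled
  top <- fP$freqs[match(paste(hap_label_alleles("B-A1-A-A"), collapse = ""),
                        fP$allele_strings)]
  expect_gt(top, 0.6); expect_lt(top, 0.9)
})

test_that("comprehensive haplotype table applies both 5% rules", {
  set.seed(9)
  fx <- simulate_cohort(sim_config(
    breeds = c(DSN = 200L), category_counts = c(intron = 0L),
    missing_rate = 0, seed = 21))
  gm <- attach_breeds(read_vcf(fx$paths$vcf), read_breed_map(fx$paths$breed_map))
  fits <- per_breed_frequencies(gm, casein_snp_positions())
  tab <- comprehensive_haplotypes(fits)
  expect_equal(colSums(tab), c(Total = 1, DSN = 1), tolerance = 1e-6)
  # CSN3*E stays below 5% in DSN -> its haplotype is pooled into Residual
  expect_false("B-A2-A-E" %in% rownames(tab))
  expect_true("Residual" %in% rownames(tab))
  expect_equal(attr(tab, "n_animals")[["DSN"]], 200)
})

test_that("theoretical haplotype counts multiply per-gene variant counts", {
  freqs <- data.frame(
    gene = rep(c("CSN1S1", "CSN2", "CSN1S2", "CSN3"), times = c(1, 3, 1, 3)),
    variant = c("B", "A1", "A2", "I", "A", "A", "B", "E"),
    breed = "DSN",
    freq = c(1, .827, .156, .017, 1, .833, .133, .034))
  expect_equal(theoretical_haplotype_count(freqs, "DSN"), 9)
  f1 <- freqs[c(1, 2, 5, 6), ]  # one variant per gene
  f1$freq <- 1
  expect_equal(theoretical_haplotype_count(f1, "DSN"), 1)
  f2 <- freqs; f2$freq[f2$variant == "I"] <- 0
  expect_equal(theoretical_haplotype_count(f2, "DSN"), 6)
})
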