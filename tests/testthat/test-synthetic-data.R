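test_that("gene models have the published geometry", {
  models <- build_gene_models()
  expect_named(models, c("CSN1S1", "CSN2", "CSN1S2", "CSN3"))
  expect_equal(models$CSN2$strand, "-")
  expect_equal(models$CSN1S1$strand, "+")
  # the kappa-casein SNP sits in a coding exon
  expect_false(is.na(coding_position(models$CSN3, 87390576)))
  # upstream window precedes the gene on the + strand
  expect_true(87157262 - models$CSN1S1$upstream[2] > 0)
  # CDS lengths divisible by 3, exons ordered and disjoint
  for (gm in models) {
    expect_equal(length(gm$cds_map) %% 3, 0)
    expect_true(all(diff(gm$exons[, 1]) > 0))
    expect_true(all(gm$exons[-1, 1] > gm$exons[-nrow(gm$exons), 2]))
  }
  # upstream window abuts the transcript on the coding strand
  expect_equal(models$CSN1S1$upstream[2] + 1, models$CSN1S1$tx[1])
  expect_equal(models$CSN2$upstream[1] - 1, models$CSN2$tx[2])
  # minus-strand gene: coding order runs against genomic order
  expect_true(all(diff(models$CSN2$cds_map) < 0))
})

test_that("reference satisfies every published codon constraint", {
  models <- build_gene_models()
  ref <- build_reference(models, seed = 1)
  st <- casein_snp_table()
  for (i in seq_len(nrow(st))) {
    a <- st[i, ]
    aa <- amino_acid_change(a$pos, a$alt, models[[a$gene]], ref)
    expect_equal(aa$ref_aa, a$aa_ref, label = paste(a$gene, a$pos, "ref"))
    expect_equal(aa$alt_aa, a$aa_alt, label = paste(a$gene, a$pos, "alt"))
    expect_equal(aa$aa_pos, a$aa_pos)
    expect_equal(aa$aa_mature, a$aa_mature)
    expect_equal(reference_base(ref, a$pos), a$ref)
  }
  # determinism
  ref2 <- build_reference(models, seed = 1)
  expect_identical(ref$seq, ref2$seq)
  expect_false(identical(ref$seq, build_reference(models, seed = 2)$seq))
})

test_that("fixture CDS translates to the published residues on both strands (independent codon oracle)", {
  models <- build_gene_models()
  ref <- build_reference(models, seed = 1)
  st <- unique(casein_snp_table()[, c("gene", "pos", "ref", "alt",
                                      "aa_ref", "aa_alt", "aa_pos")])
  for (i in seq_len(nrow(st))) {
    a <- st[i, ]
    gm <- models[[a$gene]]
    # reconstruct the codon by hand from the raw sequence
    cpos <- coding_position(gm, a$pos)
    k <- (cpos - 1) %% 3 + 1
    gpos <- genomic_position(gm, ((cpos - 1) %/% 3) * 3 + 1:3)
    for (allele in c(a$ref, a$alt)) {
      # gpos is already in coding (5'->3') order, so a minus-strand codon
      # is the base-wise complement without reversal
      bases <- reference_base(ref, gpos)
      bases[gpos == a$pos] <- allele
      codon <- if (gm$strand == "+") paste(bases, collapse = "") else
        paste(chartr("ACGT", "TGCA", bases), collapse = "")
      want <- if (allele == a$ref) a$aa_ref else a$aa_alt
      expect_equal(oracle_translate(codon), want,
                   label = paste(a$gene, a$pos, allele))
    }
  }
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(breeds = c(DSN = 30), mean_depth = 0), "mean_depth")
  expect_error(sim_config(breeds = c(DSN = 30), missing_rate = 1), "missing_rate")
  expect_error(sim_config(breeds = c(DSN = 30),
                          haplotype_freqs = list(DSN = c(`B-A1-A-A` = -1))),
               "invalid haplotype")
  p <- sim_config(breeds = c(DSN = 30))$haplotype_freqs$DSN
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("degenerate single-haplotype breed is homozygous everywhere", {
  cfg <- sim_config(breeds = c(Mono = 12L),
                    haplotype_freqs = list(Mono = c(`B-A1-A-A` = 1)),
                    category_counts = c(intron = 0L),
                    missing_rate = 0, seed = 11)
  fx <- simulate_cohort(cfg)
  gm <- read_vcf(fx$paths$vcf)
  expect_equal(nrow(gm$variants), 7)
  expect_true(all(gm$dosage %in% c(0L, 2L)))
  expect_true(all(fx$truth$hap1 == "B-A1-A-A" & fx$truth$hap2 == "B-A1-A-A"))
})

test_that("no missingness and deep coverage leave the depth filter idle", {
  cfg <- sim_config(breeds = c(DSN = 25L), missing_rate = 0, mean_depth = 1000,
                    category_counts = c(intron = 10L), seed = 5)
  fx <- simulate_cohort(cfg)
  gm <- read_vcf(fx$paths$vcf)
  filtered <- depth_trust_filter(gm, min_reads = 3)
  expect_equal(attr(filtered, "filter_report")$genotypes_masked, 0L)
  expect_identical(filtered$dosage, gm$dosage)
})

test_that("same seed gives a byte-identical VCF", {
  cfg <- small_sim_config(seed = 19)
  fx1 <- simulate_cohort(cfg)
  fx2 <- simulate_cohort(cfg)
  expect_identical(readLines(fx1$paths$vcf), readLines(fx2$paths$vcf))
})

test_that("DSN cohort reproduces the published modal haplotype frequency (stochastic)", {
  cfg <- sim_config(breeds = c(DSN = 30L), category_counts = c(intron = 0L),
                    missing_rate = 0, seed = 123)
  fx <- simulate_cohort(cfg)
  labs <- c(fx$truth$hap1, fx$truth$hap2)
  # binomial tolerance: 4 / sqrt(2 * 2n) around the Table value
  expect_lt(abs(mean(labs == "B-A1-A-A") - 0.717), 4 / sqrt(120))
})

test_that("truth haplotype counts obey the law of large numbers (n = 5000)", {
  cfg <- sim_config(breeds = c(DSN = 5000L), category_counts = c(intron = 0L),
                    missing_rate = 0, seed = 99)
  fx <- simulate_cohort(cfg)
  labs <- c(fx$truth$hap1, fx$truth$hap2)
  p <- breed_haplotype_freqs("DSN")
  emp <- table(factor(labs, levels = names(p))) / length(labs)
  expect_true(all(abs(as.numeric(emp) - p) < 0.02))
})

test_that("category round-trip: classifier reproduces generated categories exactly", {
  fx <- small_fixture()
  cls <- classify_variants(fx$variants, fx$models, fx$reference)
  expect_identical(cls$category, fx$variants$category)
})

test_that("unknown haplotype labels and oversized category counts error", {
  expect_error(hap_label_alleles("B-Z9-A-A"), "unknown haplotype label")
  cfg <- sim_config(breeds = c(DSN = 2L), category_counts = c(utr5 = 4000L),
                    seed = 1)
  expect_error(simulate_cohort(cfg), "exceeds available region length")
})
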