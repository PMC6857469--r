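test_that("built-in rules encode the published signatures", {
  rules <- builtin_rules()
  expect_setequal(unique(paste0(rules$gene, "*", rules$variant)),
                  c("CSN1S1*B", "CSN2*A1", "CSN2*A2", "CSN2*I",
                    "CSN1S2*A", "CSN3*A", "CSN3*B", "CSN3*E"))
  pick <- function(g, v) rules[rules$gene == g & rules$variant == v, ]
  expect_equal(pick("CSN2", "A1")$allele[pick("CSN2", "A1")$pos == 87181619], "T")
  expect_equal(pick("CSN3", "E")$allele[pick("CSN3", "E")$pos == 87390632], "G")
  expect_equal(pick("CSN1S2", "A")$allele, "C")
  expect_equal(pick("CSN3", "A")$allele[order(pick("CSN3", "A")$pos)],
               c("C", "C", "A"))
})

test_that("call_variant resolves signatures and reports unassigned", {
  rules <- builtin_rules()
  csn3 <- function(a) stats::setNames(a, c("87390576", "87390612", "87390632"))
  expect_equal(call_variant(csn3(c("C", "C", "A")), rules, "CSN3"), "A")
  expect_equal(call_variant(csn3(c("T", "A", "A")), rules, "CSN3"), "B")
  expect_equal(call_variant(csn3(c("C", "C", "G")), rules, "CSN3"), "E")
  expect_equal(call_variant(csn3(c("T", "C", "G")), rules, "CSN3"), "unassigned")
  csn2 <- function(a) stats::setNames(a, c("87181542", "87181619"))
  expect_equal(call_variant(csn2(c("T", "T")), rules, "CSN2"), "A1")
  expect_equal(call_variant(csn2(c("G", "G")), rules, "CSN2"), "I")
  expect_equal(call_variant(csn2(c("G", "T")), rules, "CSN2"), "unassigned")
  expect_error(call_variant(csn3(c("C", "C", "A"))[1:2], rules, "CSN3"),
               "does not cover")
})

test_that("rule validation rejects conflicts and partial signatures", {
  bad <- rbind(as.data.frame(builtin_rules()),
               data.frame(gene = "CSN3", variant = "Z",
                          pos = c(87390576L, 87390612L, 87390632L),
                          allele = c("C", "C", "A")))
  expect_error(validate_rules(bad), "identical signatures")
  part <- rbind(as.data.frame(builtin_rules()),
                data.frame(gene = "CSN3", variant = "Z",
                           pos = 87390576L, allele = "T"))
  expect_error(validate_rules(part), "does not cover")
})

test_that("rule table extension via TSV adds CSN1S1*C", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tvariant\tpos\tallele", "CSN1S1\tC\t87157262\tG"), tf)
  rules <- read_rules(tf)
  expect_equal(call_variant(c(`87157262` = "G"), rules, "CSN1S1"), "C")
  expect_equal(call_variant(c(`87157262` = "A"), rules, "CSN1S1"), "B")
})

test_that("variant frequencies marginalize, normalize and recover truth", {
  set.seed(4)
  fx <- simulate_cohort(sim_config(breeds = c(DSN = 400L),
                                   category_counts = c(intron = 0L),
                                   missing_rate = 0, seed = 17))
  gm <- attach_breeds(read_vcf(fx$paths$vcf), read_breed_map(fx$paths$breed_map))
  pf <- variant_frequencies(gm)
  # per gene per breed the frequencies sum to 1
  sums <- tapply(pf$freq, list(pf$gene, pf$breed), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # marginalization: a single-SNP-defined variant equals the direct allele
  # frequency from dosages (no missing data here)
  j <- match(87181619, gm$variants$pos)
  af_alt <- mean(gm$dosage[, j]) / 2      # G allele = A2-like background
  a1 <- pf$freq[pf$gene == "CSN2" & pf$variant == "A1" & pf$breed == "DSN"]
  a2 <- pf$freq[pf$gene == "CSN2" & pf$variant == "A2" & pf$breed == "DSN"]
  i_ <- pf$freq[pf$gene == "CSN2" & pf$variant == "I" & pf$breed == "DSN"]
  expect_equal(a1, 1 - af_alt, tolerance = 1e-6)
  expect_equal(a2 + i_, af_alt, tolerance = 1e-6)
  # truth recovery at n = 400 (haplotype table generating values)
  p <- breed_haplotype_freqs("DSN")
  truth_a1 <- sum(p * vapply(names(p), function(l)
    strsplit(l, "-")[[1]][2] %in% c("A1", "B", "F"), logical(1)))
  expect_lt(abs(a1 - truth_a1), 3 * sqrt(truth_a1 * (1 - truth_a1) / 800))
  # single-haplotype breed gives frequency 1
  fx2 <- simulate_cohort(sim_config(breeds = c(Mono = 20L),
                                    haplotype_freqs = list(Mono = c(`B-A1-A-A` = 1)),
                                    category_counts = c(intron = 0L),
                                    missing_rate = 0, seed = 2))
  gm2 <- attach_breeds(read_vcf(fx2$paths$vcf), read_breed_map(fx2$paths$breed_map))
  pf2 <- variant_frequencies(gm2)
  expect_equal(pf2$freq[pf2$gene == "CSN2" & pf2$variant == "A1" &
                          pf2$breed == "Mono"], 1, tolerance = 1e-9)
})
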