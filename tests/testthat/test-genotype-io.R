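test_that("reading the fixture reproduces the generator's matrix exactly", {
  fx <- small_fixture()
  gm <- read_vcf(fx$paths$vcf)
  expect_equal(length(gm$samples), 65)  # sum of configured breed sizes
  expect_equal(nrow(gm$variants), nrow(fx$variants))
  expect_equal(gm$variants$pos, fx$variants$pos)
  # breed map attaches and has the configured breeds
  bm <- read_breed_map(fx$paths$breed_map)
  gm <- attach_breeds(gm, bm)
  expect_setequal(unique(gm$breed_of), c("DSN", "Danish Red"))
  # dosages at the defining SNPs match the truth haplotypes
  core <- core_snps()
  truth <- fx$truth
  hap1 <- vapply(truth$hap1, hap_label_alleles, character(7))
  hap2 <- vapply(truth$hap2, hap_label_alleles, character(7))
  j <- match(core$pos, gm$variants$pos)
  for (k in seq_len(7)) {
    expected <- (hap1[k, ] == core$alt[k]) + (hap2[k, ] == core$alt[k])
    got <- gm$dosage[, j[k]]
    keep <- !is.na(got)  # generator masks some genotypes
    expect_equal(unname(got[keep]), unname(expected[keep]))
  }
})

test_that("VCF conventions: missing GT, phased GT, multiallelic skip, AD decoding", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="d">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "6\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:5,6\t./.:0,0",
    "6\t200\t.\tC\tT,G\t.\tPASS\t.\tGT:AD\t0/1:3,2\t0/0:9,0",
    "6\t300\trs1\tG\tC\t.\tPASS\t.\tGT:AD\t1|1:0,8\t0|0:7,0"
  ), tf)
  expect_message(gm <- read_vcf(tf), "1 non-biallelic-SNP record")
  expect_equal(nrow(gm$variants), 2)
  expect_equal(gm$dosage[, 1], c(S1 = 1L, S2 = NA_integer_))
  expect_equal(gm$dosage[, 2], c(S1 = 2L, S2 = 0L))  # phase ignored
  expect_equal(gm$ad_ref[1, ], c(5L, 0L))
  expect_equal(gm$ad_alt[1, ], c(6L, 8L))
  expect_equal(gm$variants$id[2], "rs1")
})

test_that("VCF errors: malformed record, no samples, region filter", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "6\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "6\tXX\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"
  ), tf)
  expect_error(read_vcf(tf), "line 3")
  tf2 <- tempfile(fileext = ".vcf")
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT", tf2)
  expect_error(read_vcf(tf2), "no samples")
  fx <- small_fixture()
  sub <- read_vcf(fx$paths$vcf, region = "6:87180000-87200000")
  expect_true(all(sub$variants$pos >= 87180000 & sub$variants$pos <= 87200000))
  expect_lt(nrow(sub$variants), nrow(fx$variants))
})

test_that("breed map contract: duplicates, empties, unmapped samples", {
  tf <- tempfile()
  writeLines(c("s1\tDSN", "s1\tDSN"), tf)
  expect_error(read_breed_map(tf), "duplicate")
  tf2 <- tempfile()
  writeLines(character(0), tf2)
  expect_error(read_breed_map(tf2))
  fx <- small_fixture()
  gm <- read_vcf(fx$paths$vcf)
  expect_error(attach_breeds(gm, c(other = "DSN")), "without breed")
})

test_that("frequency tables and trees round-trip through disk", {
  tab <- casein_haplotype_table()
  tf <- tempfile()
  write_frequency_table(tab, tf)
  back <- read_frequency_table(tf)
  expect_equal(back, tab, tolerance = 1e-6)
  # empty table -> header-only file
  empty <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("a", "b", "c")))
  write_frequency_table(empty, tf)
  expect_equal(length(readLines(tf)), 1)
  # newick with 14 leaves
  tree <- average_linkage(euclidean_distances(
    casein_haplotype_table(residual = FALSE, total = FALSE)))
  nf <- tempfile(fileext = ".nwk")
  write_newick(tree, nf)
  ph <- ape::read.tree(nf)
  expect_equal(length(ph$tip.label), 14)
  expect_equal(ph$Nnode, 13)
})

test_that("GFF3 and FASTA round-trip preserves the gene models and sequence", {
  models <- build_gene_models()
  ref <- build_reference(models, seed = 3)
  gf <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  write_gff3(models, gf)
  write_reference_fasta(ref, fa)
  models2 <- read_gene_models(gf)
  ref2 <- read_reference_fasta(fa)
  expect_equal(names(models2), names(models))
  for (g in names(models)) {
    expect_equal(models2[[g]]$exons, models[[g]]$exons)
    expect_equal(models2[[g]]$cds, models[[g]]$cds)
    expect_equal(models2[[g]]$strand, models[[g]]$strand)
    expect_equal(models2[[g]]$signal_peptide, models[[g]]$signal_peptide)
  }
  expect_identical(ref2$seq, ref$seq)
  expect_equal(ref2$offset, ref$offset)
  # the GFF3 is standard enough for rtracklayer
  gr <- rtracklayer::import(gf)
  expect_equal(sum(gr$type == "gene"), 4)
  # and the FASTA for Biostrings
  bs <- Biostrings::readDNAStringSet(fa)
  expect_equal(unname(as.character(bs[[1]])), paste(ref$seq, collapse = ""))
})
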