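# Shared fixture builders; everything is generated in code at test time.

# small two-breed cohort with a full category spread
small_sim_config <- function(seed = 7, missing_rate = 0.02, ...) {
  sim_config(breeds = c(DSN = 30L, `Danish Red` = 35L),
             category_counts = c(upstream = 5L, utr5 = 2L, intron = 30L,
                                 splice_region = 3L, synonymous = 4L,
                                 missense = 9L, utr3 = 4L),
             missing_rate = missing_rate, seed = seed, ...)
}

small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(small_sim_config())
    cache
  }
})

# core SNP table in genomic order (ref/alt per defining position)
core_snps <- function() {
  st <- casein_snp_table()
  core <- unique(st[, c("gene", "pos", "ref", "alt")])
  core[order(core$pos), ]
}

# draw an unphased dosage matrix over the 7 defining SNPs from a named
# haplotype distribution (used by EM recovery tests)
draw_dosage <- function(p, n) {
  core <- core_snps()
  alt <- stats::setNames(core$alt, as.character(core$pos))
  hapmat <- vapply(names(p), hap_label_alleles, character(nrow(core)))
  labs <- sample(names(p), 2 * n, replace = TRUE, prob = p)
  a1 <- hapmat[, labs[1:n], drop = FALSE]
  a2 <- hapmat[, labs[n + 1:n], drop = FALSE]
  t((a1 == alt) + (a2 == alt))
}

# independent hand-rolled codon table used as translation oracle
oracle_translate <- function(codon) {
  tab <- list(
    TTT="Phe",TTC="Phe",TTA="Leu",TTG="Leu",CTT="Leu",CTC="Leu",CTA="Leu",
    CTG="Leu",ATT="Ile",ATC="Ile",ATA="Ile",ATG="Met",GTT="Val",GTC="Val",
    GTA="Val",GTG="Val",TCT="Ser",TCC="Ser",TCA="Ser",TCG="Ser",CCT="Pro",
    CCC="Pro",CCA="Pro",CCG="Pro",ACT="Thr",ACC="Thr",ACA="Thr",ACG="Thr",
    GCT="Ala",GCC="Ala",GCA="Ala",GCG="Ala",TAT="Tyr",TAC="Tyr",TAA="Ter",
    TAG="Ter",CAT="His",CAC="His",CAA="Gln",CAG="Gln",AAT="Asn",AAC="Asn",
    AAA="Lys",AAG="Lys",GAT="Asp",GAC="Asp",GAA="Glu",GAG="Glu",TGT="Cys",
    TGC="Cys",TGA="Ter",TGG="Trp",CGT="Arg",CGC="Arg",CGA="Arg",CGG="Arg",
    AGT="Ser",AGC="Ser",AGA="Arg",AGG="Arg",GGT="Gly",GGC="Gly",GGA="Gly",
    GGG="Gly")
  tab[[codon]]
}

# Best log-likelihood over `n_restarts` Dirichlet(1) draws on the full
# 2^L haplotype simplex, by direct likelihood evaluation -- an oracle
# independent of the EM implementation.
oracle_max_loglik <- function(genotypes, n_restarts = 10000) {
  L <- ncol(genotypes)
  haps <- do.call(paste0, expand.grid(rep(list(c("0", "1")), L))[, L:1,
                                                                 drop = FALSE])
  pair_list <- lapply(seq_len(nrow(genotypes)), function(i) {
    prs <- enumerate_pairs(genotypes[i, ])
    list(i1 = match(prs[, 1], haps), i2 = match(prs[, 2], haps),
         c2 = ifelse(prs[, 1] == prs[, 2], 1, 2))
  })
  P <- matrix(stats::rgamma(n_restarts * length(haps), 1), n_restarts)
  P <- P / rowSums(P)
  ll <- numeric(n_restarts)
  for (pr in pair_list) {
    lik <- numeric(n_restarts)
    for (k in seq_along(pr$c2))
      lik <- lik + pr$c2[k] * P[, pr$i1[k]] * P[, pr$i2[k]]
    ll <- ll + log(lik)
  }
  max(ll)
}
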