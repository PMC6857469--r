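# caseinhap

Casein gene cluster variant annotation and protein haplotype frequency
estimation for cattle breeds.

## The problem

The four casein genes on bovine chromosome 6 — *CSN1S1*, *CSN2*, *CSN1S2*
and *CSN3*, encoding the α<sub>S1</sub>-, β-, α<sub>S2</sub>- and κ-casein
milk proteins — are tightly linked and inherited largely as a unit. Named
protein variants (e.g. β-casein *A1* vs *A2*, κ-casein *A*/*B*/*E*) are
defined by a handful of missense SNPs, and their frequencies differ
sharply between breeds with different selection histories. Comparing a
small endangered dual-purpose population such as German Black Pied cattle
(DSN) against Holstein and other breeds requires, from multi-breed VCF
genotypes:

1. **Data cleaning** — trust a genotype only with ≥ 3 reads on the two
   alleles; drop near-duplicate animals (relative Manhattan similarity
   > 0.99); keep only breeds with ≥ 30 animals; keep only variants
   polymorphic in ≥ 1 breed.
2. **Consequence classification** — assign each SNP exactly one of
   {upstream (1 kb), 5′-UTR, intron, splice region, synonymous, missense,
   3′-UTR} against strand-aware gene models, with codon-aware translation
   on the coding strand, and report SNP densities per 10 kb.
3. **Haplotype frequency estimation** — since genotypes are unphased,
   estimate multilocus haplotype frequencies per breed with the
   gene-counting EM algorithm (Excoffier–Slatkin). For haplotype pairs
   (h,k) compatible with individual *i*'s genotype, the E-step weights are
   w<sub>i</sub>(h,k) ∝ c·p<sub>h</sub>p<sub>k</sub> (c = 2 if h ≠ k) and
   the M-step sets p<sub>h</sub> to the expected haplotype count over 2n
   chromosomes; the log-likelihood is non-decreasing.
4. **Protein-variant and comprehensive-haplotype calling** — map SNP
   haplotypes to named casein variants via a signature rule table, build
   four-gene "comprehensive haplotypes" (labels like *B-A1-A-A* in gene
   order *CSN1S1-CSN2-CSN1S2-CSN3*), keeping variants with ≥ 5 %
   frequency in at least one breed and pooling rare haplotypes into a
   Residual class.
5. **Breed clustering** — Euclidean distances between per-breed frequency
   vectors, clustered with unweighted average linkage (UPGMA), exported
   as Newick.

Because the underlying multi-breed sequencing panel is access-restricted,
the package includes a first-class **synthetic cohort generator**: it
builds a reference window and GFF3 gene models for the cluster in which
the seven published missense SNP positions fall at the correct codon
offsets, draws per-animal haplotype pairs from published per-breed
haplotype frequencies, places filler SNPs per consequence category in the
published proportions (892 SNPs, 87.3 % intronic), simulates per-allele
Poisson read depths and missingness, and writes VCF/GFF3/FASTA/TSV with
full truth tables — so every stage is testable end to end.

## Worked example

```r
library(caseinhap)

cfg <- run_config(
  synthetic = sim_config(
    breeds = c(DSN = 30L, Holstein = 60L, `Danish Red` = 40L),
    category_counts = c(upstream = 6L, utr5 = 2L, intron = 60L,
                        splice_region = 3L, synonymous = 5L,
                        missense = 10L, utr3 = 4L),
    seed = 2026),
  out_dir = "example_run", seed = 2026)
res <- run_pipeline(cfg)

round(res$haplotype_table, 3)
#>          Total Danish Red   DSN Holstein
#> B-A1-A-A 0.453      0.603 0.815    0.174
#> B-A2-A-A 0.371      0.143 0.068    0.668
#> B-A1-A-B 0.071      0.054 0.097    0.071
#> B-A2-A-B 0.062      0.132 0.019    0.037
#> B-A2-A-E 0.014      0.053 0.000    0.000
#> Residual 0.029      0.014 0.000    0.050

to_newick(res$tree)
#> (Holstein:0.3917672615,(DSN:0.1305771887,Danish_Red:0.1305771887):0.2611900729);
```

Reading the output: each column is one breed's estimated distribution
over four-gene protein haplotypes (columns sum to 1, `Residual` collects
rare and unnamed haplotypes). In this simulated cohort — drawn at the
published generating frequencies — DSN is dominated by *B-A1-A-A*
(β-casein *A1* on the common *B/A/A* background, here 0.815 from 30
animals vs a generating value of 0.732), Holstein by *B-A2-A-A* (0.668),
and the dendrogram sisters DSN with Danish Red, the two breeds sharing
the *A1*-dominated profile. Per-gene views are in
`res$protein_freqs`; e.g. β-casein in DSN comes out at *A1* = 0.914,
*A2* = 0.086 for this draw, and `theoretical_haplotype_count()` reports
the number of four-gene combinations consistent with the detected
variants.

All seven report files (`variant_types.tsv`, `density.tsv`,
`protein_freqs.tsv`, `haplotype_freqs.tsv`, `breed_distances.tsv`,
`dendrogram.nwk`, `filter_report.tsv`) land in `out_dir`. The same run is
available from the shell:

```sh
Rscript exec/caseinhap run-all --out_dir example_run --seed 2026
```

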