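---
title: "Casein cluster protein haplotypes: models, estimation and design choices"
author: "caseinhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Casein cluster protein haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caseinhap)
```

## Scope and model

This package reconstructs a complete analysis path for single-nucleotide
variation in the bovine casein gene cluster (*CSN1S1*, *CSN2*, *CSN1S2*,
*CSN3* on BTA6): multi-breed VCF genotypes with per-sample allele depths
are cleaned, classified into consequence categories, reduced to named
casein protein variants and four-gene "comprehensive" protein haplotypes
with per-breed frequencies, and the breeds are clustered on those
frequency vectors. The real multi-breed sequencing panel is
access-restricted, so a synthetic cohort generator reproduces its stated
conditions and provides ground truth for every stage.

### Haplotype frequencies from unphased genotypes

Genotypes are unphased allele dosages, so haplotype frequencies are
estimated with the classical gene-counting EM algorithm. For individual
$i$, let $S_i$ be the set of haplotype pairs $(h,k)$ compatible with the
observed dosages (heterozygous loci contribute a factor 2 of phase
choices; missing loci leave both haplotypes free). With haplotype
frequencies $p$, the E-step assigns pair weights

$$w_i(h,k) \;\propto\; c\, p_h p_k, \qquad c = \begin{cases} 2 & h \ne k\\ 1 & h = k,\end{cases}$$

and the M-step re-estimates $p_h$ as the expected count of $h$ over the
$2n$ chromosomes. The observed-data log-likelihood
$\sum_i \log \sum_{(h,k) \in S_i} c\, p_h p_k$ is non-decreasing and
iteration stops when its change drops below `tol` ($10^{-8}$ by default,
`max_iter` 1000). Initialisation is uniform over the compatible
haplotypes and haplotypes are ordered lexicographically, so runs are
bit-reproducible without any RNG. Identical genotype rows are collapsed
to patterns with multiplicities, which makes the cost essentially
independent of cohort size (Holstein-sized cohorts of 541 animals fit in
well under a second).

The likelihood is multimodal in principle; the test suite therefore
checks the EM endpoint against a direct evaluation of the likelihood at
10,000 Dirichlet-random points of the full haplotype simplex on small
instances, and against the closed-form counting estimator whenever phase
is unambiguous.

Fits are run per breed independently, plus one pooled fit that supplies
the "Total" column. The original analysis used a grouped decomposition of
a pooled fit (`haplo.group`-style); per-breed fitting is simpler,
asymptotically equivalent for this use, and matches the column-wise
normalisation of the published table. Individuals with more than
`max_ambiguity` (12) unresolved loci or with more than half of a block's
loci missing are excluded from that block's fit, with a warning.

### Protein variants and comprehensive haplotypes

Named casein variants are defined by allele signatures at the seven
published missense SNPs: CSN1S1\*B; CSN2\*A1, \*A2, \*I; CSN1S2\*A;
CSN3\*A, \*B, \*E. Within a gene the signatures are mutually exclusive
over the gene's rule positions, a property `validate_rules()` enforces;
haplotypes matching no signature are reported as `unassigned`, never
silently dropped. Because the published table prints CSN2\*I's defining
SNP (Leu93) but not its background, the package fixes I = Leu93 on the
A2-like (Pro67) background — A1 = (T,T), A2 = (T,G), I = (G,G) at
(87181542, 87181619) — and ships the table as data a user TSV can extend
(see `inst/extdata/extra_rules_example.tsv`, which adds CSN1S1\*C as the
alternative Gly192 allele).

Comprehensive haplotypes are four-gene labels in chromosomal gene order
(e.g. *B-A1-A-A*). Two published inclusion rules are applied: protein
variants below 5 % frequency in every single breed are excluded (their
haplotypes move to Residual), and named haplotypes below 5 % in every
breed are pooled into Residual. `theoretical_haplotype_count()` is the
product over genes of the number of detected variants.

### Consequence classification

Each SNP inside a gene or its upstream window receives exactly one
category with precedence splice region > coding (missense/synonymous) >
UTR > intron > upstream. The splice region is the Ensembl-style window of
1–3 exonic / 1–8 intronic bases around each junction, with the canonical
donor/acceptor dinucleotides folded into it rather than kept as separate
categories. Coding SNPs are translated under the standard genetic code on
the coding strand (reverse complement for *CSN2*, which is on the minus
strand); a change to a stop codon would be reported as missense — the
category set is kept to the seven published classes, and the generator
never produces stop gains. Precursor amino-acid numbering is converted to
mature-protein numbering by subtracting the signal peptide length (15
residues for CSN1S1/CSN2/CSN1S2, 21 for CSN3), matching the published
dual numbering (e.g. His82 = His67 in mature β-casein).

SNP densities are counts per 10 kb. The exon column reports coding
variants (missense + synonymous) per 10 kb of coding sequence — the
published per-gene densities are additive in exactly this way — while
upstream and intron densities use their region lengths. The upstream
window length is a configuration knob (default 1,000 bp): the published
genome-wide upstream share is not reproducible from a fixed 1 kb window,
a discrepancy the source itself attributes to the definition of
"upstream", so no attempt is made to match it.

### Cleaning rules

Four rules run in a fixed, idempotent order: depth trust, duplicate
removal, breed floor, polymorphism.

* "At least three reads on the reference and/or alternative allele" is
  read as ref + alt total ≥ 3 — the weakest reading consistent with the
  wording; `min_reads` is configurable.
* "Relative Manhattan distance > 0.99" is treated as a *similarity*
  (the source couples it with "high genetic similarity"):
  $s(i,j) = 1 - \sum_v |d_{iv} - d_{jv}| / (2L_{ij})$ over variants
  called in both animals, which is 1 for identical dosage vectors and 0
  for opposite homozygotes; the normalisation by $2L$ is this package's
  choice. For each offending pair the member with more missing genotypes
  is removed (ties towards the lexicographically larger id) — the
  removal preference is likewise an assumption, flagged in the filter
  report header.
* Breeds under 30 animals are dropped, then variants monomorphic in
  every remaining breed are dropped. A defining missense SNP that is
  monomorphic reference in every kept breed (which happens in the
  synthetic world, where CSN1S2's SNP has no alternative carrier) is
  re-added by the pipeline as an all-reference column so that
  reference-background variants remain callable.

### Breed clustering

Euclidean distances on raw (unstandardised) frequency vectors, then
unweighted average linkage (UPGMA) with a deterministic tie-break
(lexicographically smallest pair of cluster labels, a cluster labelled by
its smallest member). Both the per-SNP alternative-allele-frequency
matrix and the haplotype table run through the same code path. Newick
export uses the ultrametric convention (node height = half the merge
height), so the patristic distance between two leaves equals the merge
height of their join; `write.tree` replaces spaces in labels with
underscores.

## The synthetic world

`sim_config()` defaults *are* the study's stated conditions:

* 14 breeds with the published sample sizes (30 DSN … 541 Holstein,
  1,821 animals in total);
* per-breed four-gene haplotype distributions taken from the published
  13-haplotype table. The Residual row's composition is unpublished, so
  it is dropped and columns renormalised — a stand-in, not the source's
  intent. This shifts the DSN modal haplotype from the printed 0.717 to
  0.717/0.980 ≈ 0.732 and Holstein's from 0.531 to 0.563; recovery tests
  therefore compare against these generating values;
* filler SNP counts per category matching the published 892-SNP
  breakdown (87.3 % intron, 5.8 % upstream, 2.2 % missense, 2.2 %
  3′-UTR, 1.2 % synonymous, 0.7 % splice region, 0.4 % 5′-UTR), with the
  seven defining SNPs counted among the 20 missense;
* per-allele read depths Poisson(`mean_depth`) per chromosome copy
  (default 5, i.e. ≈10× per genotype, so the ≥3-read filter bites
  rarely, as in deep WGS panels); heterozygote depth is the sum of the
  two per-copy draws;
* genotype missingness 2 % by default (not stated in the source; chosen
  as typical for WGS genotype calls and exercised by the EM's
  missing-data path).

Haplotype labels expand deterministically to alleles at the seven SNPs.
Variants not distinguishable at these SNPs collapse onto their
background: CSN2\*B and \*F carry the A1-like His67 allele, CSN1S2\*C/\*D
the reference Ser8 allele, so e.g. *B-B-A-B* is indistinguishable from
*B-A1-A-B* at the sequence level modelled here. Filler SNPs get a
site-specific global alternative-allele frequency drawn uniformly from
[0.05, 0.95] and Hardy–Weinberg genotypes i.i.d. across animals — no
breed structure, no linkage.

What the generator does **not** emulate: sequencing errors, indels,
multiallelic sites, linkage decay between the genes (haplotypes are
drawn as four-gene units, matching the comprehensive-haplotype framing),
breed-specific filler allele frequencies, and kinship within breeds. A
green test therefore establishes correctness of the estimation machinery
under the stated generating model — not robustness to artefacts absent
from that model, and not the genome-scale counts of the original data
(892 total / 254 DSN SNPs and the 37 observed haplotypes are properties
of the restricted panel, reproduced only as fixture proportions).

The reference window is one contiguous synthetic contig "6" covering all
four genes (offset 87,140,000 recorded in the FASTA description), so
published absolute positions work verbatim. Gene models are synthetic but
engineered: the real precursor lengths (214/224/222/190 codons), signal
peptides, strand orientations (*CSN2* on minus), and all seven missense
positions at the genomic offsets implied by their published codon
numbers; both alleles of each anchor codon translate to the published
residue pair, which `build_reference()` verifies at construction.

## Numerical and degenerate-input choices

* EM convergence is on the log-likelihood change (`tol = 1e-8`); the
  simplex is preserved exactly by construction in the M-step.
* Ties for a modal haplotype are broken lexicographically by label.
* `enumerate_pairs()` caps the number of unresolved loci at 12; the cap
  protects against exponential blow-up and is far above the 7-SNP block
  used here.
* A breed fixed for a single haplotype yields that haplotype at
  frequency 1 after one EM step; an individual heterozygous at two loci
  with a uniform start is a symmetric stationary point (all four
  haplotypes at ¼) — both covered in tests.
* Frequency tables are serialised with 6 decimals; write/read
  round-trips are stable to 1e-6.

## Monte-Carlo test calibration

The acceptance checks on recovered frequencies average over 200–1,000
seeded replicates and compare against the generating value within twice
the standard error of a *single cohort at the stated n* (estimated as
the standard deviation of the per-replicate estimates). Comparing within
2 SE of the replicate *mean* instead would reject about 5 % of seeds for
an exact estimator; measured deviations across seeds are consistent with
zero bias.

## Known limitations

* Protein variants detectable only at the protein level (e.g.
  post-translationally modified β-casein variants) are out of scope by
  construction.
* The pooled "Total" EM fit is used for the Total column; whether the
  original table pooled or averaged per-breed fits is not stated.
* No standard errors or confidence intervals on haplotype frequencies,
  and no haplotype–trait association.
* `unassigned` mass (haplotype combinations matching no signature, e.g.
  the T/G combination at the two CSN2 SNPs) is reported explicitly;
  published frequencies are over named variants only.
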