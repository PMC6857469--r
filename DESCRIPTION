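Package: caseinhap
Title: Casein Gene Cluster Variant Annotation and Protein Haplotype
    Frequency Estimation in Cattle Breeds
Version: 0.1.0
Authors@R: person("Casein", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse single-nucleotide variation in the bovine
    casein gene cluster (CSN1S1, CSN2, CSN1S2, CSN3) across cattle breeds:
    a synthetic-cohort generator that writes reference FASTA, GFF3 gene
    models and multi-breed VCFs with known protein-haplotype truth;
    genotype input/output with per-sample allele depths; the standard
    data-cleaning rules (read-depth genotype trust, similarity-based
    duplicate removal, breed-size floor, polymorphism filter); a
    strand-aware variant consequence classifier (upstream, UTR, intron,
    splice region, synonymous, missense); expectation-maximisation
    estimation of multilocus haplotype frequencies from unphased
    genotypes; mapping of SNP haplotypes to named casein protein variants
    and comprehensive four-gene protein haplotypes; and Euclidean-distance
    average-linkage clustering of breeds with Newick export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
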