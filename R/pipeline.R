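#' End-to-end run configuration
#'
#' Collects input paths (or a synthetic-cohort configuration), filter
#' thresholds, EM settings and output directory. Defaults mirror the
#' published analysis parameters: minimum 3 reads per trusted genotype,
#' 0.99 similarity threshold, breed floor of 30 animals, 5\% protein
#' variant inclusion and 5\% residual pooling thresholds.
#'
#' @param vcf,breed_map,gff3,fasta,rules input paths; leave NULL and set
#'   `synthetic` to generate a cohort instead.
#' @param synthetic a [sim_config()] or NULL.
#' @param min_reads,similarity_threshold,min_breed_size filter settings.
#' @param em_tol,em_max_iter,max_ambiguity EM settings.
#' @param min_variant_freq,residual_threshold haplotype table thresholds.
#' @param out_dir output directory.
#' @param seed integer seed (synthetic cohort only; the analysis itself is
#'   deterministic).
#' @return object of class `run_config`.
#' @export
run_config <- function(vcf = NULL, breed_map = NULL, gff3 = NULL,
                       fasta = NULL, rules = NULL, synthetic = NULL,
                       min_reads = 3, similarity_threshold = 0.99,
                       min_breed_size = 30, em_tol = 1e-8,
                       em_max_iter = 1000, max_ambiguity = 12,
                       min_variant_freq = 0.05, residual_threshold = 0.05,
                       out_dir = "caseinhap_out", seed = 1) {
  cfg <- as.list(environment())
  if (is.null(synthetic)) {
    for (p in c(vcf, breed_map, gff3, fasta))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  for (thr in c(similarity_threshold, min_variant_freq, residual_threshold))
    if (thr < 0 || thr > 1) stop("thresholds must be in [0,1]")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (synthetic generation ->) genotype input -> data cleaning ->
#' consequence classification and SNP densities -> per-gene EM and
#' protein-variant frequencies -> 7-SNP EM and the comprehensive
#' haplotype table -> breed distances and UPGMA dendrogram. Writes
#' variant_types.tsv, density.tsv, protein_freqs.tsv, haplotype_freqs.tsv,
#' breed_distances.tsv, dendrogram.nwk, filter_report.tsv and run_log.txt
#' into the output directory.
#'
#' @param config a [run_config()].
#' @return list with all stage results, invisibly; the report files are
#'   the primary output.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$out_dir, "run_log.txt")
  cat(sprintf("caseinhap %s | seed %d | %s\n",
              as.character(utils::packageVersion("caseinhap")),
              config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log)
  stage <- function(name, expr) {
    cat(sprintf("stage %s\n", name), file = log, append = TRUE)
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  if (!is.null(config$synthetic)) {
    fx <- stage("simulate", simulate_cohort(config$synthetic,
                                            file.path(config$out_dir, "fixture")))
    config$vcf <- fx$paths$vcf; config$breed_map <- fx$paths$breed_map
    config$gff3 <- fx$paths$gff3; config$fasta <- fx$paths$fasta
  }
  gm <- stage("genotype_io", {
    m <- read_vcf(config$vcf)
    attach_breeds(m, read_breed_map(config$breed_map))
  })
  models <- stage("gene_models", read_gene_models(config$gff3))
  reference <- stage("reference", read_reference_fasta(config$fasta))
  rules <- stage("rules", read_rules(config$rules))

  qc <- stage("qc_filters", qc_pipeline(gm, config$min_reads,
                                        config$similarity_threshold,
                                        config$min_breed_size))
  gm <- qc$matrix
  write_filter_report(qc$report, file.path(config$out_dir, "filter_report.tsv"))

  cls <- stage("consequence", classify_variants(gm$variants, models, reference))
  write_tsv(cls, file.path(config$out_dir, "variant_types.tsv"))
  dens <- density_table(cls, models)
  write_frequency_table(dens, file.path(config$out_dir, "density.tsv"))

  em_args <- list(tol = config$em_tol, max_iter = config$em_max_iter,
                  max_ambiguity = config$max_ambiguity)
  # rule positions absent from the cleaned matrix are monomorphic for the
  # reference allele in every kept breed; re-add them as dosage-0 columns
  # so protein variants on the reference background stay callable
  gm <- stage("augment", augment_monomorphic(gm, sort(unique(rules$pos)),
                                             reference))
  pf <- stage("protein_variants", do.call(variant_frequencies,
                                          c(list(gm, rules), em_args)))
  write_tsv(pf, file.path(config$out_dir, "protein_freqs.tsv"))

  block <- sort(unique(rules$pos))
  fits <- stage("haplotype_em", do.call(per_breed_frequencies,
                                        c(list(gm, block), em_args)))
  hap <- stage("comprehensive_haplotypes",
               comprehensive_haplotypes(fits, rules,
                                        config$min_variant_freq,
                                        config$residual_threshold))
  htab <- rbind(hap, `N animals` = attr(hap, "n_animals")[colnames(hap)])
  write_frequency_table(htab, file.path(config$out_dir, "haplotype_freqs.tsv"))

  bre <- stage("breed_cluster", {
    tab <- hap[, setdiff(colnames(hap), "Total"), drop = FALSE]
    d <- euclidean_distances(tab)
    tree <- average_linkage(d)
    list(dist = d, tree = tree)
  })
  write_frequency_table(bre$dist, file.path(config$out_dir, "breed_distances.tsv"))
  write_newick(bre$tree, file.path(config$out_dir, "dendrogram.nwk"))

  invisible(list(genotypes = gm, classified = cls, density = dens,
                 protein_freqs = pf, haplotype_table = hap,
                 distances = bre$dist, tree = bre$tree,
                 filter_report = qc$report))
}

#' Re-add filtered-out rule positions as monomorphic reference columns
#'
#' A defining SNP that is monomorphic in every kept breed is removed by
#' the polymorphism filter, yet protein-variant calling still needs the
#' locus (every animal carries the reference allele there). This inserts
#' such positions back as all-reference dosage columns, taking the
#' reference allele from the reference sequence.
#'
#' @param gm a [genotype_matrix()].
#' @param positions rule positions that must be present.
#' @param reference a `casein_reference`.
#' @return the augmented genotype matrix (unchanged if nothing is missing).
#' @export
augment_monomorphic <- function(gm, positions, reference) {
  missing_pos <- setdiff(positions, gm$variants$pos)
  if (length(missing_pos) == 0) return(gm)
  n <- length(gm$samples)
  for (p in missing_pos) {
    rb <- reference_base(reference, p)
    v <- data.frame(chrom = reference$chrom, pos = as.integer(p), id = ".",
                    ref = rb, alt = setdiff(c("A", "C", "G", "T"), rb)[1],
                    stringsAsFactors = FALSE)
    gm$variants <- rbind(gm$variants, v)
    gm$dosage <- cbind(gm$dosage, rep(0L, n))
    if (!is.null(gm$ad_ref)) gm$ad_ref <- cbind(gm$ad_ref, rep(NA_integer_, n))
    if (!is.null(gm$ad_alt)) gm$ad_alt <- cbind(gm$ad_alt, rep(NA_integer_, n))
  }
  o <- order(gm$variants$pos)
  subset_variants(gm, o)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all` (and `annotate`, `call-variants`,
#' `haplotypes`, `cluster`, which run the corresponding slice of
#' `run-all`). Options are `--key value` pairs overriding a flat
#' `key=value` config file given with `--config`.
#'
#' @param args character vector, defaults to `commandArgs(trailingOnly=TRUE)`.
#' @return exit status, invisibly.
#' @export
casein_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: caseinhap <simulate|annotate|call-variants|haplotypes|cluster|run-all>",
    "[--config FILE] [--key value ...]",
    "keys: vcf breed_map gff3 fasta rules out_dir seed n_per_breed",
    "      min_reads similarity_threshold min_breed_size em_tol",
    "      min_variant_freq residual_threshold", sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (!is.null(opts$config)) {
    kv <- readLines(opts$config)
    kv <- kv[nzchar(kv) & !startsWith(kv, "#")]
    for (line in kv) {
      p <- strsplit(line, "=", fixed = TRUE)[[1]]
      k <- trimws(p[1])
      if (is.null(opts[[k]])) opts[[k]] <- trimws(paste(p[-1], collapse = "="))
    }
    opts$config <- NULL
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  seed <- as.integer(num(opts$seed, 1))
  if (cmd == "simulate") {
    n <- as.integer(num(opts$n_per_breed, NA))
    breeds <- breed_sample_sizes()
    if (!is.na(n)) breeds[] <- n
    fx <- simulate_cohort(sim_config(breeds = breeds, seed = seed),
                          dir = if (is.null(opts$out_dir)) "caseinhap_fixture"
                                else opts$out_dir)
    message("fixture written to ", fx$dir)
    return(invisible(0L))
  }
  if (!cmd %in% c("annotate", "call-variants", "haplotypes", "cluster", "run-all"))
    stop(usage)
  cfg <- run_config(
    vcf = opts$vcf, breed_map = opts$breed_map, gff3 = opts$gff3,
    fasta = opts$fasta, rules = opts$rules,
    synthetic = if (is.null(opts$vcf)) sim_config(seed = seed) else NULL,
    min_reads = num(opts$min_reads, 3),
    similarity_threshold = num(opts$similarity_threshold, 0.99),
    min_breed_size = num(opts$min_breed_size, 30),
    em_tol = num(opts$em_tol, 1e-8),
    min_variant_freq = num(opts$min_variant_freq, 0.05),
    residual_threshold = num(opts$residual_threshold, 0.05),
    out_dir = if (is.null(opts$out_dir)) "caseinhap_out" else opts$out_dir,
    seed = seed)
  run_pipeline(cfg)
  message("reports written to ", cfg$out_dir)
  invisible(0L)
}
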