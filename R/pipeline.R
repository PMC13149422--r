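#' Default run configuration
#'
#' All tunables of the end-to-end chain with their standard values: k = 31,
#' per-sample count floor 5, MAF floor 0.01, significance tiers 5 (strict) /
#' 4 (inclusive fallback), 50 kb window half-width, 600 dpi. Simulation
#' settings describe the synthetic study: panel size, genome size, one
#' planted insertion locus, GBS read parameters and the phenotype generative
#' model.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    k = 31L, min_count = 5L, maf_min = 0.01,
    primary = 5.0, fallback = 4.0, half_width = 50000L,
    dpi = 600,
    sim = list(
      n_contigs = 1L, contig_length = 200000L,
      n_genes = 20L, gene_length = 2000L,
      n_accessions = 200L,
      causal = list(gene_index = 10L, ins_len = 31L, freq = 0.3, beta = 1.5),
      n_neutral = 40L, snp_rate = 1e-4,
      read_length = 100L, coverage = 30, error = 0,
      pheno = list(mu = 10, sigma_g2 = 0.25, sigma_e2 = 0.75,
                   treatment_effect = -1, n_replicates = 3L),
      write_fastq = FALSE))
}

#' Read / write a run configuration (YAML)
#'
#' Configurations round-trip losslessly; values absent from the file fall
#' back to [default_config()].
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  merge_cfg <- function(base, over) {
    for (nm in names(over))
      base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    base
  }
  merge_cfg(base, cfg)
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic-study pipeline
#'
#' Simulation -> k-mer matrix -> kinship + mixed-model GWAS -> two-tier
#' selection -> fragment extension, mapping, LD windows, candidate genes ->
#' phenotype indices — each stage's output written as TSV under `outdir`,
#' plus a manifest (parameters, seeds, file checksums). Identical
#' configuration and seed give identical manifest checksums.
#'
#' @param config configuration list from [default_config()] or
#'   [read_run_config()].
#' @param outdir output directory (created).
#' @param quiet suppress progress messages.
#' @return invisible list with the main in-memory objects (`reference`,
#'   `population`, `kmer_matrix`, `gwas`, `selected`, `annotated`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config = default_config(), outdir, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 2, 6)
  sim <- config$sim

  say("stage reference: %d kb genome, %d genes", sim$contig_length %/% 1000,
      sim$n_genes)
  ref <- .stage("reference", generate_reference(
    sim$n_contigs, sim$contig_length, sim$n_genes, sim$gene_length,
    seed = seeds[1]))
  fasta <- file.path(outdir, "reference.fa")
  gff <- file.path(outdir, "reference.gff3")
  write_reference(ref, fasta, gff)

  # plant the causal insertion in the middle of a chosen gene so the
  # candidate-gene stage has a recoverable truth
  g <- ref$genes[sim$causal$gene_index, ]
  causal <- data.frame(contig = g$contig,
                       pos = as.integer((g$start + g$end) / 2),
                       ins_len = sim$causal$ins_len, freq = sim$causal$freq,
                       beta = sim$causal$beta, stringsAsFactors = FALSE)
  say("stage population: %d accessions, causal locus in %s at %s:%d",
      sim$n_accessions, g$gene_id, causal$contig, causal$pos)
  pop <- .stage("population", simulate_population(
    ref, sim$n_accessions, causal, n_neutral = sim$n_neutral,
    snp_rate = sim$snp_rate, seed = seeds[2]))
  truth_path <- file.path(outdir, "truth_carriage.tsv")
  write.table(data.frame(accession_id = rownames(pop$carriage),
                         pop$carriage, check.names = FALSE),
              truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage reads+kmers: %gx coverage, %d bp reads, k=%d",
      sim$coverage, sim$read_length, config$k)
  set.seed(seeds[3])
  read_seeds <- sample.int(2^31 - 2, sim$n_accessions)
  fastq_dir <- file.path(outdir, "fastq")
  if (isTRUE(sim$write_fastq)) dir.create(fastq_dir, showWarnings = FALSE)
  reader <- function(id) {
    i <- match(id, names(pop$haplotypes))
    hap <- pop$haplotypes[[i]]
    hap <- if (length(hap) == 1) hap[[1]] else hap
    r <- simulate_gbs_reads(hap, sim$read_length, sim$coverage, sim$error,
                            seed = read_seeds[i])
    if (isTRUE(sim$write_fastq))
      write_fastq(r, file.path(fastq_dir, paste0(id, ".fastq")), id)
    r
  }
  km <- .stage("kmer_matrix", kmer_matrix_stream(
    reader, sample_ids = names(pop$haplotypes), k = config$k,
    min_count = config$min_count, maf_min = config$maf_min))
  say("  %d polymorphic k-mers retained (of %g distinct)", ncol(km$presence),
      attr(km, "n_total_kmers"))
  matrix_path <- file.path(outdir, "kmer_matrix.tsv")
  write_kmer_matrix(km, matrix_path)

  say("stage phenotypes")
  kin <- .stage("kinship", kinship_from_pa(km))
  ph <- sim$pheno
  pheno <- .stage("phenotypes", simulate_phenotypes(
    pop$truth, betas = pop$loci$beta[pop$loci$causal], K = kin$K,
    mu = ph$mu, sigma_g2 = ph$sigma_g2, sigma_e2 = ph$sigma_e2,
    treatment_effect = ph$treatment_effect, n_replicates = ph$n_replicates,
    seed = seeds[4]))
  pheno_path <- file.path(outdir, "phenotypes.tsv")
  write.table(pheno, pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage gwas: %d k-mers", ncol(km$presence))
  hp <- pheno[pheno$treatment == "HP", ]
  acc_means <- tapply(hp$value, hp$accession_id, mean)
  gwas <- .stage("gwas", run_gwas(km, acc_means, K = kin))
  gwas_path <- file.path(outdir, "gwas_results.tsv")
  write.table(gwas, gwas_path, sep = "\t", quote = FALSE, row.names = FALSE)

  sel <- .stage("selection", select_significant(gwas, config$primary,
                                                config$fallback))
  say("stage selection: %d k-mers, tier %s", nrow(sel), attr(sel, "tier"))
  ann <- list(fragments = NULL, candidates = NULL)
  if (nrow(sel)) {
    ann <- .stage("fragments", annotate_fragments(
      sel, ref, ref$genes, half_width = config$half_width))
  }
  frag_path <- file.path(outdir, "fragments.tsv")
  cand_path <- file.path(outdir, "candidates.tsv")
  write.table(if (is.null(ann$fragments))
    data.frame(fragment_id = character(0)) else ann$fragments,
    frag_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(if (is.null(ann$candidates))
    data.frame(fragment_id = character(0)) else ann$candidates,
    cand_path, sep = "\t", quote = FALSE, row.names = FALSE)
  n_cand <- if (is.null(ann$candidates)) 0L else
    length(unique(ann$candidates$gene_id))
  say("stage fragments: %d fragment rows, %d candidate gene(s)",
      if (is.null(ann$fragments)) 0L else nrow(ann$fragments), n_cand)

  say("stage manifest")
  files <- c(reference_fasta = fasta, reference_gff = gff,
             truth = truth_path, kmer_matrix = matrix_path,
             phenotypes = pheno_path, gwas = gwas_path,
             fragments = frag_path, candidates = cand_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phosgwas")),
    config = config, stage_seeds = seeds,
    outputs = lapply(seq_along(files), function(i)
      list(name = names(files)[i], path = basename(files[i]),
           md5 = unname(tools::md5sum(files[i])))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(reference = ref, population = pop, kmer_matrix = km,
                 kinship = kin, phenotypes = pheno, gwas = gwas,
                 selected = sel, annotated = ann,
                 causal = causal, causal_gene = g$gene_id,
                 manifest_path = manifest_path))
}
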