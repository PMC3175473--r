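#' Default pipeline configuration
#'
#' Thresholds mirror the analysis defaults used throughout the package:
#' genes enter codon-usage analysis at 100 codons or more; orphans are genes
#' without a nematode hit below 1e-3; class II requires a 1000-fold e-value
#' ratio; colocalization uses 30-kb flanks, 40-kb bounded-locus spans and
#' 1000 permutation iterations.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir output directory.
#' @return named list, the `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L, outdir = "pipeline_out") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    min_codons = 100L,
    orphan_e = 1e-3,
    class2_fold = 1000,
    flank = 30000L,
    max_span = 40000L,
    n_iter = 1000L,
    n_ref_genes = 400L,
    simulate = list()
  )
}

#' Read a pipeline configuration from a JSON file
#'
#' Fields present in the file override [pipeline_config()] defaults; an
#' optional `input_dir` points at files written by
#' [write_planted_genome()], otherwise inputs are simulated with the
#' parameters under `simulate`.
#'
#' @param path JSON file.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  cfg[names(user)] <- user
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full analysis end-to-end
#'
#' Stages: input simulation or loading; codon profiling and deviation
#' scoring; nearest-neighbor taxon assignment against acceptor/donor
#' references; homology-based gene status; orphan rank enrichment (KS) and
#' insect-assignment enrichment (Fisher); retrotransposon reference set,
#' flank regions and the colocalization permutation test. Per-stage TSVs, a
#' JSON summary and a parameter log are written under `config$outdir`. Runs
#' are deterministic given the config: rerunning writes byte-identical
#' summaries.
#'
#' @param config list from [pipeline_config()] / [read_pipeline_config()].
#' @return invisibly, the summary list.
#' @export
run_all <- function(config = pipeline_config()) {
  cfg <- pipeline_config()
  cfg[names(config)] <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$outdir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("codonHGT %s | R %s.%s", as.character(utils::packageVersion("codonHGT")),
       R.version$major, R.version$minor)
  logf("seed=%d min_codons=%d orphan_e=%g class2_fold=%g flank=%d n_iter=%d",
       cfg$seed, cfg$min_codons, cfg$orphan_e, cfg$class2_fold, cfg$flank,
       cfg$n_iter)

  # --- stage: inputs -------------------------------------------------------
  stage <- "inputs"
  res <- tryCatch({
    if (!is.null(cfg$input_dir)) {
      for (f in c("genes.fa", "genes.gff3", "homology.tsv", "domains.tsv",
                  "contigs.tsv")) {
        p <- file.path(cfg$input_dir, f)
        if (!file.exists(p)) stop("missing input file: ", p)
      }
      ann <- read_annotation_gff3(file.path(cfg$input_dir, "genes.gff3"))
      ctg <- utils::read.delim(file.path(cfg$input_dir, "contigs.tsv"))
      pg <- list(
        annotation = ann,
        homology = utils::read.delim(file.path(cfg$input_dir,
                                               "homology.tsv")),
        domains = utils::read.delim(file.path(cfg$input_dir, "domains.tsv")),
        contigs = stats::setNames(ctg$length, ctg$contig),
        sequences = read_cds_fasta(file.path(cfg$input_dir, "genes.fa")),
        acceptor = NULL, donor = NULL
      )
      pg
    } else {
      args <- cfg$simulate
      args$seed <- if (is.null(args$seed)) cfg$seed else args$seed
      do.call(plant_genome, args)
    }
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  pg <- res
  logf("inputs: %d genes on %d contigs", nrow(pg$annotation),
       length(pg$contigs))

  # --- stage: codon profiles ----------------------------------------------
  stage <- "codon_core"
  dev <- tryCatch({
    counts <- codon_count_matrix(pg$sequences)
    counts <- counts[rowSums(counts) >= cfg$min_codons, , drop = FALSE]
    ref <- genome_reference(counts, cfg$min_codons)
    deviation_scores(counts, ref)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  write_deviation_tsv(dev, file.path(cfg$outdir, "deviations.tsv"))
  counts <- codon_count_matrix(pg$sequences)
  counts <- counts[rowSums(counts) >= cfg$min_codons, , drop = FALSE]

  # --- stage: classification ----------------------------------------------
  stage <- "classify"
  asg <- tryCatch({
    refs <- if (!is.null(pg$acceptor)) {
      lapply(list(pg$acceptor, pg$donor), function(gen) {
        m <- codon_count_matrix(sample_genes(gen, cfg$n_ref_genes,
                                             seed = cfg$seed + 77L))
        species_profile(gen$name, gen$taxon, m, cfg$min_codons)
      })
    } else if (!is.null(cfg$references)) {
      read_reference_tsv(cfg$references)
    } else {
      stop("no reference profiles available")
    }
    assign_nearest(rscu_matrix(counts), refs)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  utils::write.table(asg, file.path(cfg$outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: homology calls ----------------------------------------------
  stage <- "homology_calls"
  status <- tryCatch({
    gene_status(pg$homology, pg$annotation$gene_id, cfg$orphan_e,
                cfg$class2_fold)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  write_status_tsv(status, file.path(cfg$outdir, "gene_status.tsv"))

  # --- stage: enrichment ---------------------------------------------------
  stage <- "enrichment_stats"
  enr <- tryCatch({
    st <- status[match(dev$gene_id, status$gene), ]
    ks <- ks_rank_enrichment(dev$d_rscu_gc, st$orphan, dev$gene_id)
    am <- asg[match(dev$gene_id, asg$gene_id), ]
    fe <- taxon_enrichment(am, st$orphan, "insect")
    list(ks = ks, fisher = fe)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  utils::write.table(enr$ks$curve, file.path(cfg$outdir,
                                             "orphan_rank_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: colocalization ----------------------------------------------
  stage <- "colocalization"
  coloc <- tryCatch({
    retro <- reference_retro_genes(pg$annotation, pg$domains, pg$homology)
    reg <- flank_regions(
      pg$annotation[pg$annotation$gene_id %in% retro, ],
      pg$contigs, cfg$flank)
    targets <- pg$annotation[pg$annotation$gene_id %in%
                               status$gene[status$orphan |
                                             status$hgt_class == "II"], ]
    perm <- permutation_enrichment(reg, targets, pg$contigs,
                                   n_iter = cfg$n_iter,
                                   seed = cfg$seed + 99L)
    list(retro = retro, regions = regions_to_df(reg), perm = perm)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  write_bed(coloc$regions, file.path(cfg$outdir, "retro_flanks.bed"))

  summary <- list(
    seed = cfg$seed,
    n_genes = nrow(pg$annotation),
    n_profiled = nrow(dev),
    n_orphans = sum(status$orphan),
    n_class1 = sum(status$hgt_class == "I"),
    n_class2 = sum(status$hgt_class == "II"),
    taxon_distribution = as.list(taxon_distribution(asg)),
    ks_p = enr$ks$p.value,
    insect_fold_orphans = enr$fisher$fold,
    insect_p_orphans = enr$fisher$p.value,
    n_retro_reference = length(coloc$retro),
    region_span = coloc$perm$region_span,
    coloc_observed = coloc$perm$observed,
    coloc_fold = coloc$perm$fold,
    coloc_fold_sd = coloc$perm$fold_sd,
    coloc_p = coloc$perm$p.value
  )
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("done: %d orphans, %d class I, %d class II, coloc fold %.3f (p=%.4g)",
       summary$n_orphans, summary$n_class1, summary$n_class2,
       summary$coloc_fold, summary$coloc_p)
  invisible(summary)
}
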