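#' Reference set of retrotransposon genes with closer insect homologs
#'
#' Genes carrying a reverse transcriptase, endonuclease or retrotransposon
#' gag domain (see [RETRO_DOMAINS]) whose best insect e-value is strictly
#' smaller than their best nematode e-value. Domain-carrying genes without
#' any homology row are excluded with a warning.
#'
#' @param annotations data.frame with at least gene_id (used to intersect
#'   with the other tables).
#' @param domain_table data.frame with columns gene, accession.
#' @param homology_table homology table (gene, taxon, evalue).
#' @param accessions domain accessions defining retrotransposon genes.
#' @return character vector of gene ids.
#' @export
reference_retro_genes <- function(annotations, domain_table, homology_table,
                                  accessions = RETRO_DOMAINS) {
  dom_genes <- unique(domain_table$gene[domain_table$accession %in%
                                          accessions])
  dom_genes <- dom_genes[dom_genes %in% annotations$gene_id]
  if (!length(dom_genes)) return(character(0))
  in_hom <- dom_genes %in% homology_table$gene
  if (any(!in_hom)) {
    warning(sum(!in_hom), " domain-carrying genes lack homology rows; ",
            "excluded")
  }
  dom_genes <- dom_genes[in_hom]
  bh <- best_hits(validate_homology(homology_table), dom_genes)
  sort(dom_genes[bh$insect < bh$nematode])
}

#' Merged flank regions around anchor genes
#'
#' Each gene interval is extended by `flank` bp on both sides, clipped to the
#' contig bounds, and overlapping intervals on the same contig are merged.
#'
#' @param genes data.frame with contig, start, end (0-based half-open).
#' @param contigs named numeric vector of contig lengths.
#' @param flank extension in bp on each side.
#' @return A [GenomicRanges::GRanges] of merged regions (0-based half-open
#'   stored as 1-based closed internally); `sum(width())` is the total span.
#' @export
flank_regions <- function(genes, contigs, flank = 30000L) {
  if (any(!genes$contig %in% names(contigs))) {
    stop("gene on unknown contig: ",
         paste(unique(setdiff(genes$contig, names(contigs))), collapse = ", "))
  }
  len <- contigs[genes$contig]
  if (any(genes$start < 0 | genes$end > len | genes$start >= genes$end)) {
    stop("gene coordinates outside contig bounds")
  }
  start0 <- pmax(genes$start - flank, 0)
  end0 <- pmin(genes$end + flank, len)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(genes$contig, levels = sort(names(contigs))),
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
  GenomicRanges::reduce(sort(gr))
}

#' Regions as a 0-based half-open data.frame
#' @param regions GRanges from [flank_regions()].
#' @return data.frame contig, start, end, width.
#' @export
regions_to_df <- function(regions) {
  data.frame(contig = as.character(GenomicRanges::seqnames(regions)),
             start = GenomicRanges::start(regions) - 1L,
             end = GenomicRanges::end(regions),
             width = GenomicRanges::width(regions),
             stringsAsFactors = FALSE)
}

#' Export regions or loci as BED
#' @param df data.frame with contig, start, end (0-based half-open).
#' @param path output path.
#' @param names optional feature names.
#' @export
write_bed <- function(df, path, names = NULL) {
  bed <- data.frame(df$contig, df$start, df$end)
  if (!is.null(names)) bed$name <- names
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Scan for retrotransposon-bounded loci
#'
#' Reports pairs of an endonuclease gene and a reverse-transcriptase gene on
#' the same contig and strand spanning at most `max_span` bp, together with
#' the genes fully contained between them. Boundary orientation must match
#' (same strand for both boundary genes).
#'
#' @param annotations data.frame with gene_id, contig, start, end, strand.
#' @param endo_genes,rt_genes gene ids of endonuclease and reverse
#'   transcriptase genes.
#' @param max_span maximum locus span (bp) from the outer boundary starts to
#'   ends.
#' @return data.frame with one row per locus: contig, strand, start, end,
#'   span, endo_gene, rt_gene, n_embedded, embedded (comma-separated ids).
#' @export
scan_bounded_loci <- function(annotations, endo_genes, rt_genes,
                              max_span = 40000L) {
  ann <- annotations[order(annotations$contig, annotations$start,
                           annotations$gene_id), , drop = FALSE]
  endo <- ann[ann$gene_id %in% endo_genes, , drop = FALSE]
  rt <- ann[ann$gene_id %in% rt_genes, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(endo))) {
    e <- endo[i, ]
    cand <- rt[rt$contig == e$contig & rt$strand == e$strand &
                 rt$gene_id != e$gene_id, , drop = FALSE]
    if (!nrow(cand)) next
    lo <- pmin(e$start, cand$start)
    hi <- pmax(e$end, cand$end)
    ok <- (hi - lo) <= max_span
    for (j in which(ok)) {
      left_end <- min(e$end, cand$end[j])
      right_start <- max(e$start, cand$start[j])
      inside <- ann$contig == e$contig &
        ann$start >= left_end & ann$end <= right_start &
        !(ann$gene_id %in% c(e$gene_id, cand$gene_id[j]))
      emb <- ann$gene_id[inside]
      out[[length(out) + 1L]] <- data.frame(
        contig = e$contig, strand = e$strand,
        start = lo[j], end = hi[j], span = hi[j] - lo[j],
        endo_gene = e$gene_id, rt_gene = cand$gene_id[j],
        n_embedded = length(emb),
        embedded = paste(emb, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      span = integer(0), endo_gene = character(0),
                      rt_gene = character(0), n_embedded = integer(0),
                      embedded = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$endo_gene, res$rt_gene), ,
      drop = FALSE]
}

# count target starts falling inside a set of intervals (0-based half-open)
.count_in_regions <- function(targets, reg_df) {
  n <- 0L
  for (ctg in unique(reg_df$contig)) {
    r <- reg_df[reg_df$contig == ctg, , drop = FALSE]
    pts <- targets$start[targets$contig == ctg]
    if (!length(pts) || !nrow(r)) next
    bounds <- as.vector(rbind(r$start, r$end))    # sorted, disjoint
    n <- n + sum(findInterval(pts, bounds) %% 2L == 1L)
  }
  n
}

#' Permutation test for target-gene enrichment in a region set
#'
#' The observed statistic is the number of target genes whose start
#' coordinate lies inside the regions. Each iteration places intervals with
#' the identical multiset of lengths uniformly over the contigs (position
#' uniform among all feasible starts, mutually non-overlapping, by rejection
#' sampling) and recounts. The empirical p-value uses the add-one correction
#' `(1 + #{count >= observed}) / (1 + n_iter)` so it is never zero; fold
#' enrichment is observed over the mean sampled count, with a dispersion
#' given by the standard deviation of the per-iteration ratios
#' observed / sampled (iterations with a zero sampled count are dropped from
#' the dispersion only).
#'
#' @param regions GRanges from [flank_regions()] or a data.frame with contig,
#'   start, end (0-based half-open, disjoint).
#' @param targets data.frame with contig, start for the target genes.
#' @param contigs named numeric vector of contig lengths.
#' @param n_iter number of permutation iterations.
#' @param seed integer seed.
#' @param exclude_observed if TRUE, sampled intervals may not overlap the
#'   observed regions (default FALSE: the null covers the whole genome).
#' @param max_fail abort after this many consecutive rejection failures.
#' @return list of class `permutation_result`: observed, sampled_mean,
#'   sampled_sd, fold, fold_sd, p.value, n_iter, seed, region_span,
#'   genome_span.
#' @export
permutation_enrichment <- function(regions, targets, contigs,
                                   n_iter = 1000L, seed = 1L,
                                   exclude_observed = FALSE,
                                   max_fail = 1000L) {
  reg <- if (is.data.frame(regions)) regions else regions_to_df(regions)
  reg <- reg[order(reg$contig, reg$start), , drop = FALSE]
  lens <- reg$end - reg$start
  genome_span <- sum(contigs)
  if (sum(lens) >= genome_span / 2) {
    stop("regions cover more than half the genome; sampling infeasible")
  }
  observed <- .count_in_regions(targets, reg)

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ctg_names <- names(contigs)
  counts <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    placed <- list()  # per contig: 2-col matrix of start,end
    fails <- 0L
    for (L in lens[sample.int(length(lens))]) {   # random placement order
      repeat {
        feas <- pmax(contigs - L + 1, 0)
        if (exclude_observed) {
          # feasibility unchanged; overlap check below handles exclusion
        }
        ctg <- sample(ctg_names, 1L, prob = feas)
        s <- floor(stats::runif(1, 0, feas[ctg]))
        e <- s + L
        ok <- TRUE
        pl <- placed[[ctg]]
        if (!is.null(pl) && any(s < pl[, 2] & e > pl[, 1])) ok <- FALSE
        if (ok && exclude_observed) {
          r <- reg[reg$contig == ctg, , drop = FALSE]
          if (nrow(r) && any(s < r$end & e > r$start)) ok <- FALSE
        }
        if (ok) {
          placed[[ctg]] <- rbind(pl, c(s, e))
          fails <- 0L
          break
        }
        fails <- fails + 1L
        if (fails >= max_fail) {
          stop("rejection sampling failed ", max_fail,
               " consecutive times; regions too dense for the genome")
        }
      }
    }
    samp <- do.call(rbind, lapply(names(placed), function(ctg) {
      data.frame(contig = ctg, start = placed[[ctg]][, 1],
                 end = placed[[ctg]][, 2], stringsAsFactors = FALSE)
    }))
    samp <- samp[order(samp$contig, samp$start), , drop = FALSE]
    counts[it] <- .count_in_regions(targets, samp)
  }
  ratios <- observed / counts[counts > 0]
  structure(list(
    observed = observed,
    sampled_mean = mean(counts),
    sampled_sd = stats::sd(counts),
    fold = observed / mean(counts),
    fold_sd = stats::sd(ratios),
    p.value = (1 + sum(counts >= observed)) / (1 + n_iter),
    n_iter = n_iter,
    seed = seed,
    region_span = sum(lens),
    genome_span = genome_span
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation enrichment: observed %d vs sampled %.2f +/- %.2f\n",
    x$observed, x$sampled_mean, x$sampled_sd))
  cat(sprintf("  fold %.3f +/- %.3f, p = %.4g (%d iterations, seed %d)\n",
              x$fold, x$fold_sd, x$p.value, x$n_iter, x$seed))
  invisible(x)
}
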