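#' Rank-based orphan enrichment with a one-sample KS test
#'
#' Genes are sorted by decreasing deviation score (ties broken by gene id so
#' the ranking is stable and order-independent). If orphans were unrelated to
#' atypical codon usage their normalized ranks (rank / N) would be uniform on
#' (0, 1); a one-sample Kolmogorov-Smirnov test against Uniform(0,1)
#' quantifies the departure, and the cumulative orphan fraction along the
#' ranking gives the enrichment curve.
#'
#' @param deviations numeric deviation score per gene (larger = more
#'   atypical).
#' @param orphan logical vector, same length.
#' @param gene_id optional ids used for the stable tie-break (defaults to
#'   index order).
#' @return list with `curve` (data.frame rank, cutoff_fraction,
#'   cum_orphan_fraction), `baseline` (overall orphan fraction), `D`,
#'   `p.value` (two-sided), and `direction` (`"enriched"` when orphans sit at
#'   atypically small ranks, i.e. among the most deviant genes).
#' @export
ks_rank_enrichment <- function(deviations, orphan, gene_id = NULL) {
  n <- length(deviations)
  stopifnot(length(orphan) == n)
  if (sum(orphan) < 2L || sum(!orphan) < 2L) {
    stop("need at least 2 orphans and 2 non-orphans")
  }
  if (is.null(gene_id)) gene_id <- sprintf("g%08d", seq_len(n))
  if (length(unique(deviations)) == 1L) {
    warning("constant deviation scores; ranking driven by gene ids only")
  }
  o <- order(-deviations, gene_id)
  orphan_sorted <- orphan[o]
  ranks <- which(orphan_sorted) / n
  ks <- suppressWarnings(stats::ks.test(ranks, "punif"))
  ecdf_ranks <- stats::ecdf(ranks)
  grid <- seq_len(n) / n
  direction <- if (max(ecdf_ranks(grid) - grid) >=
                   max(grid - ecdf_ranks(grid))) "enriched" else "depleted"
  curve <- data.frame(
    rank = seq_len(n),
    cutoff_fraction = grid,
    cum_orphan_fraction = cumsum(orphan_sorted) / seq_len(n)
  )
  list(curve = curve, baseline = mean(orphan),
       D = unname(ks$statistic), p.value = ks$p.value,
       direction = direction)
}

#' Two-sided Fisher's exact test with fold enrichment
#'
#' The 2x2 table is (a, b; c, d) with `a` the in-set successes. The p-value
#' is the sum of all hypergeometric point probabilities (at the fixed
#' margins) not exceeding that of the observed table; fold enrichment is the
#' in-set success fraction over the overall success fraction.
#'
#' @param a,b,c,d non-negative integer cell counts; all four margins must be
#'   positive.
#' @return list with `a`, `n_set` (= a + b), `n_success` (= a + c), `total`,
#'   `fold`, `p.value`, `test`.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("all margins of the 2x2 table must be positive")
  }
  n <- a + b + c + d
  m <- a + c                       # successes overall
  k <- a + b                       # set size
  xs <- max(0L, k - (n - m)):min(k, m)
  probs <- stats::dhyper(xs, m, n - m, k)
  p_obs <- stats::dhyper(a, m, n - m, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  fold <- (a / (a + b)) / (m / n)
  list(a = a, n_set = k, n_success = m, total = n, fold = fold,
       p.value = p, test = "fisher_two_sided")
}

#' Wilcoxon rank-sum comparison of two groups of relative distances
#'
#' Two-sample, two-sided Wilcoxon rank-sum test. The exact distribution is
#' used for small tie-free samples and the normal approximation with tie
#' correction otherwise (the [stats::wilcox.test()] policy).
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param alternative as in [stats::wilcox.test()].
#' @return list with `W`, `p.value`, sample sizes.
#' @export
ranksum_compare <- function(x, y, alternative = "two.sided") {
  if (length(x) < 2L || length(y) < 2L) stop("both samples need >= 2 values")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  list(W = unname(wt$statistic), p.value = wt$p.value,
       n_x = length(x), n_y = length(y))
}

#' Domain enrichment in a gene set (hypergeometric upper tail)
#'
#' For each domain, fold enrichment is the in-set domain frequency over the
#' genomewide frequency and the p-value is the hypergeometric probability of
#' observing at least the in-set count when drawing `set_size` genes from the
#' genome. Benjamini-Hochberg adjusted q-values are reported alongside.
#'
#' @param set_counts named integer vector: genes carrying each domain inside
#'   the set.
#' @param genome_counts named integer vector: genes carrying each domain
#'   genomewide (must cover all domains in `set_counts` with counts >= the
#'   set counts).
#' @param set_size,genome_size number of genes in the set / genome.
#' @return data.frame domain, n_set, n_genome, fold, p.value, q.value,
#'   ordered by decreasing n_set.
#' @export
domain_enrichment <- function(set_counts, genome_counts, set_size,
                              genome_size) {
  doms <- names(set_counts)
  if (is.null(doms)) stop("set_counts must be named by domain accession")
  ng <- genome_counts[doms]
  if (any(is.na(ng)) || any(ng == 0)) {
    stop("domain absent genomewide: ",
         paste(doms[is.na(ng) | ng == 0], collapse = ", "))
  }
  if (any(set_counts > ng)) stop("set counts exceed genomewide counts")
  if (any(set_counts > set_size)) stop("set counts exceed set size")
  fold <- (set_counts / set_size) / (ng / genome_size)
  p <- stats::phyper(set_counts - 1, ng, genome_size - ng, set_size,
                     lower.tail = FALSE)
  out <- data.frame(domain = doms,
                    n_set = as.integer(set_counts),
                    n_genome = as.integer(ng),
                    fold = unname(fold),
                    p.value = unname(p),
                    q.value = unname(stats::p.adjust(p, "BH")),
                    stringsAsFactors = FALSE)
  out[order(-out$n_set, out$domain), , drop = FALSE]
}

#' Enrichment of a predicted taxon among a gene subset
#'
#' Convenience wrapper building the 2x2 table "in subset x assigned to
#' `taxon`" from an assignment table and a logical subset indicator, then
#' calling [fisher_enrichment()].
#'
#' @param assignments data.frame from [assign_nearest()].
#' @param in_set logical vector aligned with `assignments`.
#' @param taxon taxon group tested for enrichment.
#' @return as [fisher_enrichment()], plus `taxon`.
#' @export
taxon_enrichment <- function(assignments, in_set, taxon) {
  stopifnot(nrow(assignments) == length(in_set))
  hit <- assignments$taxon == taxon
  res <- fisher_enrichment(sum(in_set & hit), sum(in_set & !hit),
                           sum(!in_set & hit), sum(!in_set & !hit))
  res$taxon <- taxon
  res
}
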