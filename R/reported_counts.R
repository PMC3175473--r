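#' Published summary counts for the P. pacificus HGT analysis
#'
#' Headline gene counts from the Pristionchus pacificus genome analysis that
#' this package's methods operationalize, usable as worked-example inputs:
#' the full computation needs the real genome and the 71-species panel, but
#' the summary fractions and fold enrichments derive from these counts
#' alone.
#'
#' @format A named list:
#' \describe{
#'   \item{n_genes}{24231 predicted protein-coding genes.}
#'   \item{n_with_nematode_homolog}{15014 genes with a nematode homolog at
#'     e-value < 0.001.}
#'   \item{n_orphans}{9217 genes without one.}
#'   \item{n_class1}{205 class I HGT candidates.}
#'   \item{n_class2}{304 class II HGT candidates.}
#'   \item{n_candidates}{509 HGT candidates in total.}
#'   \item{n_conserved_any}{218 candidates conserved in at least one sister
#'     Pristionchus genome.}
#'   \item{n_conserved_both}{105 candidates conserved in both.}
#'   \item{pct_insect_all_genes}{4.8, percent of all genes assigned
#'     insect-like codon usage.}
#'   \item{pct_insect_orphans}{8.5, percent among orphan genes.}
#'   \item{pct_insect_class2}{9.0, percent among class II candidates.}
#' }
#' @export
ppacificus_counts <- list(
  n_genes = 24231L,
  n_with_nematode_homolog = 15014L,
  n_orphans = 9217L,
  n_class1 = 205L,
  n_class2 = 304L,
  n_candidates = 509L,
  n_conserved_any = 218L,
  n_conserved_both = 105L,
  pct_insect_all_genes = 4.8,
  pct_insect_orphans = 8.5,
  pct_insect_class2 = 9.0
)
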