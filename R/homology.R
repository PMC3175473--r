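#' Read a homology table from BLAST tabular output
#'
#' Accepts either the standard 12-column BLAST tabular format (outfmt 6;
#' query, subject, identity, ..., e-value, bitscore) plus a subject-to-taxon
#' map, or a pre-reduced table with columns gene, subject, taxon, evalue.
#' Rows with negative e-values are rejected.
#'
#' @param path path to the tabular file (no header for 12-column BLAST
#'   output; header `gene subject taxon evalue` for the reduced form).
#' @param taxon_map optional two-column data.frame or TSV path (subject,
#'   taxon) mapping subject identifiers to taxon groups; required for raw
#'   BLAST input. Subjects missing from the map get taxon `"other"`.
#' @return data.frame with columns gene, subject, taxon, evalue.
#' @export
read_homology <- function(path, taxon_map = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^gene\t", first)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 11L) stop("expected >= 11 columns of BLAST tabular output")
    if (is.null(taxon_map)) stop("taxon_map is required for raw BLAST input")
    if (is.character(taxon_map)) {
      taxon_map <- utils::read.delim(taxon_map, stringsAsFactors = FALSE)
    }
    df <- data.frame(gene = raw[[1L]], subject = raw[[2L]],
                     taxon = taxon_map$taxon[match(raw[[2L]],
                                                   taxon_map$subject)],
                     evalue = raw[[11L]], stringsAsFactors = FALSE)
    df$taxon[is.na(df$taxon)] <- "other"
  }
  validate_homology(df)
}

#' Validate a homology table
#'
#' @param df data.frame with gene, subject (optional), taxon, evalue.
#' @return the validated table (negative-e-value rows removed with warning).
#' @export
validate_homology <- function(df) {
  stopifnot(all(c("gene", "taxon", "evalue") %in% names(df)))
  bad_tax <- !df$taxon %in% HOMOLOGY_GROUPS
  if (any(bad_tax)) {
    stop("unknown taxon labels: ",
         paste(unique(df$taxon[bad_tax]), collapse = ", "))
  }
  neg <- df$evalue < 0
  if (any(neg)) {
    warning("rejecting ", sum(neg), " rows with negative e-values")
    df <- df[!neg, , drop = FALSE]
  }
  df
}

#' Best (minimum) e-value per gene and taxon group
#'
#' Duplicate rows and row order are irrelevant by construction.
#'
#' @param table homology table (gene, taxon, evalue).
#' @param genes character vector of the full gene universe; genes without any
#'   row get `Inf` throughout.
#' @return data.frame with one row per gene and one numeric column per
#'   homology group (`Inf` where no hit exists).
#' @export
best_hits <- function(table, genes) {
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (grp in HOMOLOGY_GROUPS) {
    sub <- table[table$taxon == grp, , drop = FALSE]
    if (nrow(sub)) {
      m <- tapply(sub$evalue, sub$gene, min)
      v <- unname(m[match(genes, names(m))])
      v[is.na(v)] <- Inf
    } else {
      v <- rep(Inf, length(genes))
    }
    out[[grp]] <- v
  }
  out
}

#' Call orphan genes
#'
#' A gene is an orphan when no nematode-group hit with e-value strictly below
#' `threshold` exists (genes absent from the table are vacuously orphans).
#'
#' @param table homology table.
#' @param genes gene universe.
#' @param threshold e-value threshold (strict `<`).
#' @return logical vector named by gene.
#' @export
call_orphans <- function(table, genes, threshold = 1e-3) {
  bh <- best_hits(validate_homology(table), genes)
  stats::setNames(!(bh$nematode < threshold), genes)
}

#' Call class I HGT candidates
#'
#' Class I: orphan genes (no nematode homolog) with an insect hit at e-value
#' strictly below `insect_threshold`.
#'
#' @inheritParams call_orphans
#' @param insect_threshold e-value threshold for the insect hit (strict `<`).
#' @return character vector of class I gene ids.
#' @export
call_class1 <- function(table, genes, threshold = 1e-3,
                        insect_threshold = 1e-3) {
  bh <- best_hits(validate_homology(table), genes)
  orphan <- !(bh$nematode < threshold)
  genes[orphan & bh$insect < insect_threshold]
}

#' Call class II HGT candidates
#'
#' Class II: genes with nematode homologs whose best insect e-value is at
#' least `fold` times smaller than the best nematode e-value (boundary
#' inclusive). E-values of exactly zero are floored at `floor` before the
#' ratio so it is always defined.
#'
#' @inheritParams call_orphans
#' @param fold required e-value ratio (default 1000).
#' @param floor replacement for zero e-values.
#' @return character vector of class II gene ids.
#' @export
call_class2 <- function(table, genes, threshold = 1e-3, fold = 1000,
                        floor = 1e-180) {
  bh <- best_hits(validate_homology(table), genes)
  nem <- pmax(bh$nematode, floor)
  ins <- pmax(bh$insect, floor)
  not_orphan <- bh$nematode < threshold
  # tiny relative slack keeps the inclusive boundary exact under floating
  # point (1e-6 / 1000 does not equal 1e-9 in doubles)
  genes[not_orphan & is.finite(ins) & ins <= (nem / fold) * (1 + 1e-9)]
}

#' Conservation flags in sister Pristionchus genomes
#'
#' @param table homology table containing rows for the taxon labels
#'   `pristionchus_entomophagus` and `pristionchus_maupasi`.
#' @param candidates gene ids of HGT candidates.
#' @param threshold e-value threshold (strict `<`).
#' @return list with `flags` (data.frame gene, conserved_entomophagus,
#'   conserved_maupasi) and `summary` (n_candidates, conserved_any,
#'   conserved_both).
#' @export
conservation_flags <- function(table, candidates, threshold = 1e-3) {
  bh <- best_hits(validate_homology(table), candidates)
  ento <- bh$pristionchus_entomophagus < threshold
  maup <- bh$pristionchus_maupasi < threshold
  flags <- data.frame(gene = candidates,
                      conserved_entomophagus = ento,
                      conserved_maupasi = maup,
                      stringsAsFactors = FALSE)
  list(flags = flags,
       summary = c(n_candidates = length(candidates),
                   conserved_any = sum(ento | maup),
                   conserved_both = sum(ento & maup)))
}

#' Full per-gene homology status
#'
#' Combines orphan status, the mutually exclusive HGT class (`none`, `I`,
#' `II`) and conservation flags into one table. Class I implies orphan;
#' class II implies non-orphan; every gene gets exactly one class.
#'
#' @inheritParams call_orphans
#' @param class2_fold e-value ratio for class II.
#' @return data.frame gene, orphan, hgt_class, conserved_entomophagus,
#'   conserved_maupasi.
#' @export
gene_status <- function(table, genes, threshold = 1e-3, class2_fold = 1000) {
  table <- validate_homology(table)
  orphan <- call_orphans(table, genes, threshold)
  c1 <- call_class1(table, genes, threshold)
  c2 <- call_class2(table, genes, threshold, class2_fold)
  cls <- rep("none", length(genes))
  cls[genes %in% c1] <- "I"
  cls[genes %in% c2] <- "II"
  cons <- conservation_flags(table, genes, threshold)$flags
  data.frame(gene = genes,
             orphan = unname(orphan),
             hgt_class = cls,
             conserved_entomophagus = cons$conserved_entomophagus,
             conserved_maupasi = cons$conserved_maupasi,
             stringsAsFactors = FALSE)
}

#' Write gene status as TSV
#' @param status data.frame from [gene_status()].
#' @param path output file.
#' @export
write_status_tsv <- function(status, path) {
  utils::write.table(status, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
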