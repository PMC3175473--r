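#' Build a species reference profile
#'
#' @param name species name.
#' @param taxon taxonomic group, one of [TAXON_GROUPS].
#' @param counts codon count matrix of the species' genes, or a precomputed
#'   profile matrix/vector (attribute `normalized` required).
#' @param min_codons length filter applied to count input.
#' @return A `species_profile`: list with `species`, `taxon`, `profile`
#'   (GC-normalized genomewide profile), `n_genes`.
#' @export
species_profile <- function(name, taxon, counts, min_codons = 100L) {
  taxon <- match.arg(taxon, TAXON_GROUPS)
  if (is.matrix(counts) && is.null(attr(counts, "normalized"))) {
    ref <- genome_reference(counts, min_codons = min_codons)
    prof <- ref$profile_gc
    n <- ref$n_genes
  } else if (is.matrix(counts)) {
    prof <- genomewide_profile(counts)
    n <- nrow(counts)
  } else {
    .profile_flag(counts)
    prof <- counts
    n <- 1L
  }
  structure(list(species = name, taxon = taxon, profile = prof,
                 n_genes = n),
            class = "species_profile")
}

.ref_matrix <- function(refs) {
  if (length(refs) == 0L) stop("empty reference set")
  stopifnot(all(vapply(refs, inherits, logical(1), "species_profile")))
  species <- vapply(refs, `[[`, character(1), "species")
  o <- order(species)                     # lexicographic tie rule
  refs <- refs[o]
  m <- do.call(rbind, lapply(refs, function(r) as.numeric(r$profile)))
  rownames(m) <- species[o]
  flags <- vapply(refs, function(r) .profile_flag(r$profile), logical(1))
  if (length(unique(flags)) != 1L) stop("mixed normalization flags in refs")
  list(m = m, species = species[o],
       taxon = vapply(refs, `[[`, character(1), "taxon"),
       normalized = flags[[1L]])
}

#' Assign genes to the nearest species by codon-usage distance
#'
#' Each gene is assigned to the reference species with the smallest Euclidean
#' distance between RSCU profiles; ties are broken by lexicographic species
#' name, so the result is deterministic and independent of reference order.
#'
#' @param profiles genes x 59 profile matrix (e.g. from [rscu_matrix()]) or a
#'   single profile vector.
#' @param refs list of [species_profile()] objects.
#' @return data.frame gene_id, species, taxon, distance; the full gene x
#'   species distance matrix is attached as attribute `"distances"`.
#' @export
assign_nearest <- function(profiles, refs) {
  if (!is.matrix(profiles)) {
    profiles <- matrix(as.numeric(profiles), nrow = 1L,
                       dimnames = list("gene", NULL))
    attr(profiles, "normalized") <- TRUE
  }
  rr <- .ref_matrix(refs)
  if (!identical(.profile_flag(profiles), rr$normalized)) {
    stop("gene and reference profiles differ in normalization flag")
  }
  # squared distances via the expansion |x - r|^2 = |x|^2 - 2 x.r + |r|^2
  cross <- profiles %*% t(rr$m)
  d2 <- outer(rowSums(profiles^2), rowSums(rr$m^2), "+") - 2 * cross
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  best <- apply(d, 1L, which.min)         # first minimum = lexicographic tie
  out <- data.frame(
    gene_id = rownames(profiles),
    species = rr$species[best],
    taxon = rr$taxon[best],
    distance = d[cbind(seq_len(nrow(d)), best)],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  dimnames(d) <- list(rownames(profiles), rr$species)
  attr(out, "distances") <- d
  out
}

#' Fractions of genes assigned to each taxonomic group
#'
#' @param assignments data.frame from [assign_nearest()].
#' @return named numeric vector over [TAXON_GROUPS], summing to 1.
#' @export
taxon_distribution <- function(assignments) {
  if (nrow(assignments) == 0L) stop("no assignments")
  tab <- table(factor(assignments$taxon, levels = TAXON_GROUPS))
  as.vector(tab / sum(tab)) -> fr
  stats::setNames(fr, TAXON_GROUPS)
}

#' Cross-validated accuracy of nearest-neighbor species prediction
#'
#' In each replicate, `n_val` genes are drawn at random from every species
#' into a validation set; species profiles are rebuilt from the remaining
#' genes only (validation genes are held out of their own species' profile),
#' and validation genes are assigned with [assign_nearest()]. Accuracy is the
#' fraction of correct predictions, reported as mean and standard deviation
#' over replicates at the species and the taxonomic-group level, together
#' with a row-normalized taxon confusion matrix (percent).
#'
#' @param species_sets named list; each element is a list with `taxon` and
#'   `counts` (codon count matrix of that species' genes).
#' @param n_val validation genes drawn per species and replicate.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param min_codons gene length filter (codons, inclusive).
#' @return list with `species_accuracy`, `taxon_accuracy` (each mean/sd),
#'   `confusion_mean`, `confusion_sd` (taxon x taxon, rows sum to 100),
#'   `n_species`, `reps`.
#' @export
crossvalidate <- function(species_sets, n_val = 333L, reps = 10L, seed = 1L,
                          min_codons = 100L) {
  stopifnot(length(species_sets) >= 2L, !is.null(names(species_sets)))
  prep <- lapply(names(species_sets), function(sp) {
    s <- species_sets[[sp]]
    m <- .as_count_matrix(s$counts)
    m <- m[rowSums(m) >= min_codons, , drop = FALSE]
    list(name = sp, taxon = match.arg(s$taxon, TAXON_GROUPS), counts = m,
         gc3 = gc3(m))
  })
  enough <- vapply(prep, function(p) nrow(p$counts) > n_val, logical(1))
  if (!all(enough)) {
    warning("excluding species with <= n_val qualifying genes: ",
            paste(vapply(prep[!enough], `[[`, character(1), "name"),
                  collapse = ", "))
    prep <- prep[enough]
  }
  if (length(prep) < 2L) stop("need at least two species with enough genes")
  profiles <- lapply(prep, function(p) rscu_matrix(p$counts, p$gc3))
  taxa <- vapply(prep, `[[`, character(1), "taxon")
  names(profiles) <- vapply(prep, `[[`, character(1), "name")

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lev <- TAXON_GROUPS
  conf <- array(0, dim = c(length(lev), length(lev), reps),
                dimnames = list(lev, lev, NULL))
  acc_sp <- acc_tx <- numeric(reps)
  for (r in seq_len(reps)) {
    val_idx <- lapply(profiles, function(pm) sample(nrow(pm), n_val))
    refs <- lapply(seq_along(profiles), function(i) {
      pm <- profiles[[i]][-val_idx[[i]], , drop = FALSE]
      attr(pm, "normalized") <- TRUE
      species_profile(names(profiles)[i], taxa[i], genomewide_profile(pm))
    })
    val <- do.call(rbind, lapply(seq_along(profiles), function(i) {
      profiles[[i]][val_idx[[i]], , drop = FALSE]
    }))
    attr(val, "normalized") <- TRUE
    truth_sp <- rep(names(profiles), each = n_val)
    truth_tx <- rep(taxa, each = n_val)
    asg <- assign_nearest(val, refs)
    acc_sp[r] <- mean(asg$species == truth_sp)
    acc_tx[r] <- mean(asg$taxon == truth_tx)
    tab <- table(factor(truth_tx, lev), factor(asg$taxon, lev))
    rs <- rowSums(tab)
    rs[rs == 0] <- 1
    conf[, , r] <- 100 * sweep(as.matrix(tab), 1L, rs, "/") *
      (rowSums(tab) > 0)
  }
  list(
    species_accuracy = c(mean = mean(acc_sp), sd = stats::sd(acc_sp)),
    taxon_accuracy = c(mean = mean(acc_tx), sd = stats::sd(acc_tx)),
    confusion_mean = apply(conf, c(1, 2), mean),
    confusion_sd = apply(conf, c(1, 2), stats::sd),
    n_species = length(profiles),
    reps = reps
  )
}

#' Relative codon-usage distance to three reference profiles
#'
#' For each gene, the Euclidean distances to a self (nematode), a fungal and
#' an insect reference profile are expressed relative to their sum, so the
#' three relative distances add to exactly 1 and lie in \[0, 1\]. A small
#' relative distance to the insect reference indicates insect-like codon
#' usage regardless of the gene's absolute atypicality.
#'
#' @param profiles genes x 59 profile matrix or single profile vector.
#' @param ref_self,ref_fungal,ref_insect reference profiles (vectors or
#'   `species_profile` objects).
#' @return data.frame gene_id, rel_self, rel_fungal, rel_insect.
#' @export
relative_distance <- function(profiles, ref_self, ref_fungal, ref_insect) {
  get_prof <- function(r) if (inherits(r, "species_profile")) r$profile else r
  refs <- lapply(list(ref_self, ref_fungal, ref_insect), get_prof)
  if (!is.matrix(profiles)) {
    profiles <- matrix(as.numeric(profiles), nrow = 1L,
                       dimnames = list("gene", NULL))
  }
  d <- vapply(refs, function(rf) {
    sqrt(rowSums(sweep(profiles, 2L, as.numeric(rf))^2))
  }, numeric(nrow(profiles)))
  if (nrow(profiles) == 1L) d <- matrix(d, nrow = 1L)
  tot <- rowSums(d)
  if (any(tot == 0)) stop("gene equidistant at zero from all three references")
  data.frame(
    gene_id = if (!is.null(rownames(profiles))) rownames(profiles)
              else paste0("gene", seq_len(nrow(profiles))),
    rel_self = d[, 1] / tot,
    rel_fungal = d[, 2] / tot,
    rel_insect = d[, 3] / tot,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Serialize / read species reference profiles as TSV
#'
#' One row per species: species, taxon, n_genes, then the 59 codon columns.
#' @param refs list of `species_profile` objects.
#' @param path file path.
#' @export
write_reference_tsv <- function(refs, path) {
  rows <- lapply(refs, function(r) {
    data.frame(species = r$species, taxon = r$taxon, n_genes = r$n_genes,
               t(as.numeric(r$profile)), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df)[-(1:3)] <- .gcode()$profile_codons
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_tsv
#' @return `read_reference_tsv()` returns a list of `species_profile`
#'   objects (profiles flagged GC-normalized).
#' @export
read_reference_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  codons <- .gcode()$profile_codons
  lapply(seq_len(nrow(df)), function(i) {
    prof <- as.numeric(df[i, codons])
    names(prof) <- codons
    attr(prof, "normalized") <- TRUE
    structure(list(species = df$species[i], taxon = df$taxon[i],
                   profile = prof, n_genes = df$n_genes[i]),
              class = "species_profile")
  })
}
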