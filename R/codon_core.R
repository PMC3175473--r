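#' Read coding sequences from a FASTA file
#'
#' Identifiers are truncated at the first whitespace, following BLAST/EMBOSS
#' convention.
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] with cleaned names.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Count in-frame codons for a set of coding sequences
#'
#' Sequences must be A/C/G/T only and of length divisible by 3. A single
#' terminal stop codon is trimmed before counting; any remaining in-frame stop
#' codon is an error (the sequence is not a clean CDS).
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector) of
#'   coding sequences.
#' @return Integer matrix, one row per gene, one column per sense codon (61
#'   columns); `rowSums()` gives the per-gene codon total.
#' @export
codon_count_matrix <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (length(seqs) == 0L) stop("no sequences supplied")
  if (is.null(names(seqs))) names(seqs) <- paste0("gene", seq_along(seqs))
  gc <- .gcode()
  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  bad <- af[, "other"] > 0
  if (any(bad)) {
    stop("non-A/C/G/T characters in: ",
         paste(utils::head(names(seqs)[bad], 5), collapse = ", "))
  }
  w <- Biostrings::width(seqs)
  if (any(w %% 3L != 0L)) {
    stop("sequence length not divisible by 3 for: ",
         paste(utils::head(names(seqs)[w %% 3L != 0L], 5), collapse = ", "))
  }
  if (any(w < 3L)) stop("empty coding sequence")
  # trim a single terminal stop codon where present
  last <- as.character(Biostrings::subseq(seqs, start = w - 2L, end = w))
  has_stop <- last %in% gc$stop_codons
  if (any(has_stop)) {
    seqs[has_stop] <- Biostrings::subseq(seqs[has_stop], start = 1L,
                                         end = w[has_stop] - 3L)
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("sequence consists of a lone stop codon")
  }
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = 3L, step = 3L)
  internal <- rowSums(counts[, gc$stop_codons, drop = FALSE])
  if (any(internal > 0)) {
    stop("internal stop codon in: ",
         paste(utils::head(names(seqs)[internal > 0], 5), collapse = ", "))
  }
  out <- counts[, names(gc$code), drop = FALSE]
  rownames(out) <- names(seqs)
  storage.mode(out) <- "integer"
  out
}

#' Codon counts for a single coding sequence
#'
#' @param seq a single CDS as a character string or `DNAString`.
#' @param id optional gene identifier.
#' @return A `codon_counts` object: list with `id`, `counts` (named integer
#'   vector over the 61 sense codons) and `n_codons`.
#' @examples
#' extract_codons("ATGGAAGAG")$counts[c("ATG", "GAA", "GAG")]
#' @export
extract_codons <- function(seq, id = "gene") {
  m <- codon_count_matrix(stats::setNames(as.character(seq), id))
  structure(
    list(id = id, counts = m[1L, ], n_codons = sum(m[1L, ])),
    class = "codon_counts"
  )
}

.as_count_matrix <- function(counts) {
  if (inherits(counts, "codon_counts")) {
    m <- matrix(counts$counts, nrow = 1L,
                dimnames = list(counts$id, names(counts$counts)))
    return(m)
  }
  if (!is.matrix(counts)) stop("expected a codon count matrix or codon_counts")
  counts
}

#' GC3: fraction of codons whose third nucleotide is G or C
#'
#' Computed over all counted codons (terminal stop already excluded),
#' including the single-codon families Met and Trp.
#'
#' @param counts a `codon_counts` object or codon count matrix.
#' @return numeric vector in \[0, 1\], one value per gene.
#' @export
gc3 <- function(counts) {
  m <- .as_count_matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("gene with zero codons")
  gc <- .gcode()
  rowSums(m[, names(which(gc$third_gc)), drop = FALSE]) / tot
}

#' Expected codon frequencies under a per-nucleotide GC model
#'
#' For a codon with `k` G/C nucleotides, the unnormalized probability is
#' `GC3^k * (1 - GC3)^(3 - k)`; expected frequencies are these probabilities
#' renormalized within each synonymous family. GC3 is clamped to
#' \[0.01, 0.99\] so that no expected frequency is exactly zero.
#'
#' @param gc3 numeric vector of GC3 fractions (one per gene).
#' @return A list with `gc3` (clamped), `p` (genes x 61 unnormalized codon
#'   probabilities) and `f_exp` (genes x 61 expected frequencies; each
#'   family's row slice sums to 1).
#' @examples
#' m <- expected_codon_freq(0.7)
#' m$f_exp[, "GAG"]  # 0.7: G/C-ending codon of a two-fold family
#' @export
expected_codon_freq <- function(gc3) {
  g <- pmin(pmax(gc3, 0.01), 0.99)
  gc <- .gcode()
  k <- gc$gc_k
  p <- vapply(k, function(kk) g^kk * (1 - g)^(3 - kk), numeric(length(g)))
  if (length(g) == 1L) p <- matrix(p, nrow = 1L, dimnames = list(NULL, names(k)))
  f_exp <- p
  for (fam in gc$families) {
    z <- rowSums(p[, fam, drop = FALSE])
    f_exp[, fam] <- p[, fam, drop = FALSE] / z
  }
  list(gc3 = g, p = p, f_exp = f_exp)
}

#' RSCU profiles (classic or GC-normalized) for a set of genes
#'
#' The profile is the ratio of observed within-family codon frequencies to
#' expected frequencies, over the 59 codons of degenerate families. With
#' `normalized = TRUE` the expectation follows the gene's GC3 via
#' [expected_codon_freq()]; with `normalized = FALSE` all synonymous codons
#' are taken as equally likely (classic RSCU up to the family-size factor,
#' expressed on the same observed/expected scale). Families with zero
#' occurrences in a gene are imputed to the neutral value 1.
#'
#' @param counts codon count matrix (genes x 61) or `codon_counts`.
#' @param gc3 optional numeric vector of GC3 values; computed from `counts`
#'   when omitted.
#' @param normalized logical; GC-normalized (default) or classic expectation.
#' @return numeric matrix genes x 59 with attribute `normalized`.
#' @export
rscu_matrix <- function(counts, gc3 = NULL, normalized = TRUE) {
  m <- .as_count_matrix(counts)
  gc <- .gcode()
  if (is.null(gc3)) gc3 <- gc3(m)
  if (length(gc3) != nrow(m)) stop("gc3 length must match number of genes")
  if (normalized) {
    f_exp <- expected_codon_freq(gc3)$f_exp
  } else {
    sizes <- lengths(gc$families)[gc$family_of]
    f_exp <- matrix(1 / sizes, nrow = nrow(m), ncol = ncol(m), byrow = TRUE,
                    dimnames = list(rownames(m), names(gc$code)))
  }
  out <- matrix(1, nrow = nrow(m), ncol = length(gc$profile_codons),
                dimnames = list(rownames(m), gc$profile_codons))
  for (fam in gc$families) {
    if (length(fam) < 2L) next
    tot <- rowSums(m[, fam, drop = FALSE])
    fob <- m[, fam, drop = FALSE] / tot          # NaN where family absent
    r <- fob / f_exp[, fam, drop = FALSE]
    r[tot == 0, ] <- 1                           # neutral imputation
    out[, fam] <- r
  }
  attr(out, "normalized") <- normalized
  out
}

#' @rdname rscu_matrix
#' @param ... passed to [rscu_matrix()].
#' @return `rscu_profile()` returns a single named numeric vector of length
#'   59 with attribute `normalized`.
#' @export
rscu_profile <- function(counts, ...) {
  m <- rscu_matrix(counts, ...)
  out <- m[1L, ]
  attr(out, "normalized") <- attr(m, "normalized")
  out
}

.profile_flag <- function(x) {
  f <- attr(x, "normalized")
  if (is.null(f)) stop("profile lacks a 'normalized' flag")
  f
}

#' Average genomewide RSCU profile
#'
#' Unweighted componentwise mean of per-gene profiles.
#'
#' @param profiles a genes x 59 matrix from [rscu_matrix()], or a list of
#'   profile vectors with identical `normalized` flags.
#' @return named numeric vector of length 59 with attribute `normalized`.
#' @export
genomewide_profile <- function(profiles) {
  if (is.list(profiles)) {
    if (length(profiles) == 0L) stop("no profiles supplied")
    flags <- vapply(profiles, .profile_flag, logical(1))
    if (length(unique(flags)) != 1L) stop("mixed normalization flags")
    m <- do.call(rbind, profiles)
    attr(m, "normalized") <- flags[[1L]]
    profiles <- m
  }
  if (nrow(profiles) == 0L) stop("no profiles supplied")
  out <- colMeans(profiles)
  attr(out, "normalized") <- .profile_flag(profiles)
  out
}

#' Euclidean distance between two RSCU profiles
#'
#' @param x,y profile vectors with matching `normalized` flags.
#' @return non-negative scalar.
#' @export
profile_distance <- function(x, y) {
  if (!identical(.profile_flag(x), .profile_flag(y))) {
    stop("profiles have different normalization flags")
  }
  sqrt(sum((as.numeric(x) - as.numeric(y))^2))
}

#' Genomewide reference for deviation scoring
#'
#' Builds the average classic profile, the average GC-normalized profile and
#' the mean per-gene GC3 from a codon count matrix (genes below `min_codons`
#' are excluded first).
#'
#' @param counts codon count matrix.
#' @param min_codons minimum gene length in codons (inclusive).
#' @return list with `profile_classic`, `profile_gc`, `mean_gc3`, `n_genes`.
#' @export
genome_reference <- function(counts, min_codons = 100L) {
  m <- .as_count_matrix(counts)
  keep <- rowSums(m) >= min_codons
  if (!any(keep)) stop("no gene passes the length filter")
  m <- m[keep, , drop = FALSE]
  g <- gc3(m)
  list(
    profile_classic = genomewide_profile(rscu_matrix(m, g, normalized = FALSE)),
    profile_gc = genomewide_profile(rscu_matrix(m, g, normalized = TRUE)),
    mean_gc3 = mean(g),
    n_genes = nrow(m)
  )
}

#' Per-gene deviation from the genomewide average
#'
#' Three measures per gene: Euclidean distance of the classic RSCU profile to
#' the genomewide classic profile (`d_rscu`), the same for GC-normalized
#' profiles (`d_rscu_gc`), and the absolute difference between the gene's GC3
#' and the genomewide mean GC3 (`d_gc3`).
#'
#' @param counts codon count matrix (or `codon_counts`).
#' @param reference a list from [genome_reference()].
#' @return data.frame with columns gene_id, n_codons, gc3, d_rscu,
#'   d_rscu_gc, d_gc3.
#' @export
deviation_scores <- function(counts, reference) {
  m <- .as_count_matrix(counts)
  g <- gc3(m)
  pc <- rscu_matrix(m, g, normalized = FALSE)
  pg <- rscu_matrix(m, g, normalized = TRUE)
  d1 <- sqrt(rowSums(sweep(pc, 2, as.numeric(reference$profile_classic))^2))
  d2 <- sqrt(rowSums(sweep(pg, 2, as.numeric(reference$profile_gc))^2))
  data.frame(
    gene_id = rownames(m),
    n_codons = rowSums(m),
    gc3 = g,
    d_rscu = unname(d1),
    d_rscu_gc = unname(d2),
    d_gc3 = abs(g - reference$mean_gc3),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation with input validation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y, method = "pearson")
}

#' Write per-gene deviation scores as TSV
#'
#' @param scores data.frame from [deviation_scores()].
#' @param path output file.
#' @export
write_deviation_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
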