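#' The standard genetic code and synonymous codon families
#'
#' Returns the bookkeeping object used throughout the package: the standard
#' codon to amino-acid map, the partition of the 61 sense codons into
#' synonymous families, the 59-codon universe used for RSCU profiles
#' (degenerate families only; ATG and TGG carry no synonymous information and
#' are excluded), per-codon G+C counts, and a flag for codons whose third
#' nucleotide is G or C.
#'
#' @return A list with components:
#' \describe{
#'   \item{code}{named character vector, codon -> one-letter amino acid
#'     (61 sense codons).}
#'   \item{stop_codons}{the three stop codons.}
#'   \item{families}{named list of character vectors partitioning the sense
#'     codons by amino acid.}
#'   \item{profile_codons}{the 59 codons of degenerate families, in fixed
#'     order.}
#'   \item{family_of}{named character vector, codon -> amino acid, restricted
#'     to sense codons.}
#'   \item{gc_k}{named integer vector, number of G/C nucleotides per sense
#'     codon (the exponent of the per-nucleotide GC model).}
#'   \item{third_gc}{named logical vector, TRUE when the codon's third base is
#'     G or C.}
#' }
#' @examples
#' gc <- genetic_code()
#' length(gc$profile_codons)  # 59
#' @export
genetic_code <- function() {
  .gcode()
}

.codon_env <- new.env(parent = emptyenv())

.build_genetic_code <- function() {
  full <- Biostrings::GENETIC_CODE
  stops <- names(full)[full == "*"]
  sense <- full[full != "*"]
  fam <- split(names(sense), sense)
  fam_sizes <- lengths(fam)
  profile_aa <- names(fam_sizes)[fam_sizes >= 2L]
  profile_codons <- sort(unlist(fam[profile_aa], use.names = FALSE))
  bases <- function(i) substr(names(sense), i, i)
  gc_k <- (bases(1) %in% c("G", "C")) + (bases(2) %in% c("G", "C")) +
    (bases(3) %in% c("G", "C"))
  gc_k <- stats::setNames(as.integer(gc_k), names(sense))
  third_gc <- stats::setNames(bases(3) %in% c("G", "C"), names(sense))
  family_of <- stats::setNames(unname(sense), names(sense))
  list(
    code = sense,
    stop_codons = stops,
    families = fam,
    profile_codons = profile_codons,
    family_of = family_of,
    gc_k = gc_k,
    third_gc = third_gc
  )
}

.onLoad <- function(libname, pkgname) {
  assign("code", .build_genetic_code(), envir = .codon_env)
}

# internal shorthand used across modules
.gcode <- function() {
  if (is.null(.codon_env$code)) {
    assign("code", .build_genetic_code(), envir = .codon_env)
  }
  .codon_env$code
}

#' Closed set of taxonomic groups used for species references
#' @export
TAXON_GROUPS <- c("insect", "bacteria", "amoebozoa", "fungi", "nematode",
                  "plant")

#' Taxon labels recognised in homology tables
#' @export
HOMOLOGY_GROUPS <- c("nematode", "insect", "pristionchus_entomophagus",
                     "pristionchus_maupasi", "other")

#' Pfam accessions defining retrotransposon genes
#'
#' Reverse transcriptase, endonuclease/exonuclease/phosphatase, and
#' retrotransposon gag domains.
#' @export
RETRO_DOMAINS <- c(
  reverse_transcriptase = "PF00078.20",
  endonuclease = "PF03372.16",
  gag = "PF03732.10"
)
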