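#' Longest stop-free codon run in each of the six reading frames
#'
#' Frames +1, +2, +3 scan the input sequence at offsets 0, 1, 2; frames -1,
#' -2, -3 scan the reverse complement at the same offsets. A run is a maximal
#' stretch of consecutive codons containing neither a stop codon nor any
#' ambiguous base (codons with N break runs). Coordinates are 0-based
#' half-open in the frame's own orientation, i.e. on the reverse complement
#' for minus frames.
#'
#' @param est a single sequence (character or `DNAString`); may contain N.
#' @return data.frame with columns frame (+1..+3, -1..-3), longest_bp,
#'   start, end (coordinates of the leftmost longest run; NA when no run
#'   exists).
#' @export
six_frame_longest <- function(est) {
  s <- toupper(as.character(est))
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  stops <- .gcode()$stop_codons
  scan_one <- function(seqchr, offset) {
    L <- nchar(seqchr)
    n_cod <- (L - offset) %/% 3L
    if (n_cod < 1L) {
      return(c(longest = 0L, start = NA_integer_, end = NA_integer_))
    }
    starts <- offset + 3L * (seq_len(n_cod) - 1L) + 1L
    cods <- substring(seqchr, starts, starts + 2L)
    ok <- !(cods %in% stops) & !grepl("[^ACGT]", cods)
    r <- rle(ok)
    if (!any(r$values)) {
      return(c(longest = 0L, start = NA_integer_, end = NA_integer_))
    }
    lens <- r$lengths
    best_len <- max(lens[r$values])
    idx <- which(r$values & lens == best_len)[1L]
    first_cod <- if (idx == 1L) 1L else sum(lens[seq_len(idx - 1L)]) + 1L
    start0 <- offset + 3L * (first_cod - 1L)
    c(longest = 3L * best_len, start = start0, end = start0 + 3L * best_len)
  }
  res <- rbind(
    scan_one(s, 0L), scan_one(s, 1L), scan_one(s, 2L),
    scan_one(rc, 0L), scan_one(rc, 1L), scan_one(rc, 2L)
  )
  data.frame(frame = c(1L, 2L, 3L, -1L, -2L, -3L),
             longest_bp = res[, "longest"],
             start = res[, "start"],
             end = res[, "end"])
}

#' Select a CDS from an EST by the six-frame longest-ORF rule
#'
#' The longest stop-free run among the six frame maxima is accepted as a CDS
#' when it is at least `min_len` bp long and the second-longest frame maximum
#' is at most `second_max` bp. Two frames tied for the longest run make the
#' call ambiguous and the EST is rejected. For an accepted call the primary
#' CDS starts at the first codon of the run; an alternative CDS anchored at
#' the last (3'-most) in-frame ATG inside the run is reported alongside.
#'
#' @param est a single sequence (character or `DNAString`).
#' @param id identifier for the output.
#' @param min_len minimum length (bp) of the longest run.
#' @param second_max maximum length (bp) allowed for the second-longest frame
#'   maximum.
#' @return A one-row data.frame (`cds_call`): est_id, frame, start, end,
#'   longest_len, second_longest_len, accepted, ambiguous, cds, cds_atg
#'   (NA when no in-frame ATG exists in the run). Coordinates follow
#'   [six_frame_longest()].
#' @export
select_cds <- function(est, id = "est", min_len = 300L, second_max = 150L) {
  sf <- six_frame_longest(est)
  o <- order(-sf$longest_bp, abs(sf$frame), -sign(sf$frame))
  top <- sf[o[1L], ]
  second <- sf$longest_bp[o[2L]]
  ambiguous <- sum(sf$longest_bp == top$longest_bp) > 1L && top$longest_bp > 0L
  accepted <- !ambiguous && top$longest_bp >= min_len && second <= second_max
  cds <- cds_atg <- NA_character_
  if (accepted) {
    s <- toupper(as.character(est))
    oriented <- if (top$frame > 0) s else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    cds <- substr(oriented, top$start + 1L, top$end)
    cod_starts <- seq(1L, nchar(cds) - 2L, by = 3L)
    atg <- cod_starts[substring(cds, cod_starts, cod_starts + 2L) == "ATG"]
    if (length(atg)) cds_atg <- substr(cds, atg[length(atg)], nchar(cds))
  }
  data.frame(est_id = id,
             frame = top$frame,
             start = top$start,
             end = top$end,
             longest_len = top$longest_bp,
             second_longest_len = second,
             accepted = accepted,
             ambiguous = ambiguous,
             cds = cds,
             cds_atg = cds_atg,
             stringsAsFactors = FALSE)
}

#' Run the CDS selection over a set of ESTs
#'
#' @param ests a [Biostrings::DNAStringSet] or named character vector.
#' @param min_len,second_max as in [select_cds()].
#' @return data.frame with one [select_cds()] row per EST.
#' @export
find_cds <- function(ests, min_len = 300L, second_max = 150L) {
  if (is.character(ests) && is.null(names(ests))) {
    names(ests) <- paste0("est", seq_along(ests))
  }
  seqs <- as.character(ests)
  ids <- names(ests)
  do.call(rbind, lapply(seq_along(seqs), function(i) {
    select_cds(seqs[i], ids[i], min_len, second_max)
  }))
}

#' Write accepted CDS calls as FASTA plus a TSV of all calls
#'
#' @param calls data.frame from [find_cds()].
#' @param fasta_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_cds_calls <- function(calls, fasta_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    acc <- calls[calls$accepted, , drop = FALSE]
    if (nrow(acc)) {
      seqs <- Biostrings::DNAStringSet(acc$cds)
      names(seqs) <- acc$est_id
      Biostrings::writeXStringSet(seqs, fasta_path)
    } else {
      cat("", file = fasta_path)
    }
  }
  if (!is.null(tsv_path)) {
    utils::write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(calls)
}
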