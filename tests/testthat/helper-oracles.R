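# Independent brute-force oracles. These deliberately use a different style
# (character loops, explicit sums) from the package implementation.

# sliding-window codon counter over a character string
oracle_count_codons <- function(s) {
  out <- integer(0)
  i <- 1L
  while (i + 2L <= nchar(s)) {
    cod <- substr(s, i, i + 2L)
    out[cod] <- if (is.na(out[cod])) 1L else out[cod] + 1L
    i <- i + 3L
  }
  out
}

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, point probabilities from log-factorials
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  lp <- function(x) {
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(n + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) -
      lgamma(c1 - x + 1) - lgamma(r2 - c1 + x + 1)
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lp(xs))
  p_obs <- exp(lp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# naive per-frame longest stop-free run, codon-by-codon with a counter
oracle_frame_runs <- function(s) {
  stops <- c("TAA", "TAG", "TGA")
  revcomp <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  res <- data.frame(frame = c(1, 2, 3, -1, -2, -3), longest_bp = 0L)
  for (r in seq_len(6)) {
    fr <- res$frame[r]
    seqc <- if (fr > 0) s else revcomp(s)
    off <- abs(fr) - 1L
    best <- 0L; run <- 0L
    i <- off + 1L
    while (i + 2L <= nchar(seqc)) {
      cod <- substr(seqc, i, i + 2L)
      if (cod %in% stops || grepl("[^ACGT]", cod)) {
        run <- 0L
      } else {
        run <- run + 1L
        if (run > best) best <- run
      }
      i <- i + 3L
    }
    res$longest_bp[r] <- 3L * best
  }
  res
}

# plain-loop Euclidean distance
oracle_euclid <- function(x, y) {
  x <- unname(as.numeric(x)); y <- unname(as.numeric(y))
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s)
}

# random stop-free CDS of n codons (uniform over sense codons)
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(genetic_code()$code)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

neutral_profile <- function() {
  p <- rep(1, 59)
  names(p) <- genetic_code()$profile_codons
  attr(p, "normalized") <- TRUE
  p
}

profile_from <- function(values, normalized = TRUE) {
  p <- values
  names(p) <- genetic_code()$profile_codons
  attr(p, "normalized") <- normalized
  p
}
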