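# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Construct a synthetic species generator
#'
#' A species is defined by a target GC-normalized RSCU profile `1 + s * u`,
#' where `u` is a seed-derived unit direction in the 59-dimensional profile
#' space and `s = separation` is the Euclidean distance of the species'
#' analytic profile from the neutral all-ones profile. Within every
#' synonymous family, `u` is constrained to be orthogonal to the expected
#' frequencies at the species' mean GC3 (so the target is a valid profile:
#' expected-frequency-weighted family sums stay 1) and to their GC3-ending
#' component (so species preferences carry no net third-position G/C signal
#' and the realized GC3 of sampled genes is not shifted by the preference
#' direction). The second constraint removes all preference signal from
#' two-fold families, whose only degree of freedom is the third base. Genes are sampled codon by
#' codon with within-family probabilities proportional to the target profile
#' times the GC3-dependent expected frequencies, so the expected
#' GC-normalized RSCU profile of a gene equals the target regardless of the
#' gene's GC3 — the decorrelation property that GC normalization is meant to
#' deliver.
#'
#' @param name species name.
#' @param taxon taxonomic group, one of [TAXON_GROUPS].
#' @param gc3_mean,gc3_sd mean and sd of the per-gene GC3 distribution
#'   (normal, clamped to \[0.05, 0.95\]).
#' @param separation Euclidean distance of the analytic profile from the
#'   neutral profile; 0 gives the neutral species.
#' @param seed integer seed fixing the direction `u`.
#' @param len_range gene length range in codons (uniform, inclusive).
#' @return A `species_generator` object.
#' @export
make_species <- function(name, taxon, gc3_mean = 0.5, gc3_sd = 0.05,
                         separation = 0, seed = 1L,
                         len_range = c(100L, 500L)) {
  taxon <- match.arg(taxon, TAXON_GROUPS)
  stopifnot(separation >= 0, gc3_mean > 0.05, gc3_mean < 0.95,
            gc3_sd >= 0, len_range[1] >= 100L)
  gc <- .gcode()
  codons <- gc$profile_codons
  fexp <- expected_codon_freq(gc3_mean)$f_exp[1L, codons]
  third_gc <- gc$third_gc[codons]
  u <- .with_seed(seed, {
    z <- stats::setNames(stats::rnorm(length(codons)), codons)
    for (fam in gc$families) {
      fam <- intersect(fam, codons)
      if (length(fam) < 2L) next
      # remove the components that would change the family's expected
      # frequency sum or its expected third-position G/C contribution:
      # species preferences must not carry a net GC3 signal
      basis <- cbind(fexp[fam], fexp[fam] * third_gc[fam])
      q <- qr(basis)
      qmat <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
      z[fam] <- z[fam] - qmat %*% crossprod(qmat, z[fam])
    }
    nz <- sqrt(sum(z^2))
    if (nz < 1e-8) stop("degenerate direction seed")
    z / nz
  })
  w <- 1 + separation * u
  if (min(w) < 0.02) {
    stop("infeasible separation for this seed: target profile not positive")
  }
  structure(list(name = name, taxon = taxon, weights = w,
                 gc3_mean = gc3_mean, gc3_sd = gc3_sd,
                 separation = separation, seed = seed,
                 len_range = as.integer(len_range)),
            class = "species_generator")
}

#' Analytic expected RSCU profile of a species generator
#'
#' Closed-form expectation of the GC-normalized RSCU profile of genes
#' sampled at the species' mean GC3, in the long-gene limit. For finite
#' genes the profile computed from counts uses the gene's estimated GC3,
#' whose sampling noise adds a small convexity bias to the observed/expected
#' ratio; the bias shrinks with gene length (about the inverse of the codon
#' count) and is immaterial above ~1000 codons.
#'
#' @param gen a `species_generator`.
#' @return named numeric vector (59 codons) with attribute
#'   `normalized = TRUE`.
#' @export
analytic_profile <- function(gen) {
  stopifnot(inherits(gen, "species_generator"))
  out <- gen$weights
  attr(out, "normalized") <- TRUE
  out
}

# per-codon sampling probabilities over the 59-codon universe at GC3 = g;
# family picked proportional to its size, codon within family proportional
# to weight * expected frequency
.codon_probs <- function(gen, g) {
  gc <- .gcode()
  codons <- gc$profile_codons
  fexp <- expected_codon_freq(g)$f_exp[1L, codons]
  p <- stats::setNames(numeric(length(codons)), codons)
  for (fam in gc$families) {
    fam <- intersect(fam, codons)
    if (length(fam) < 2L) next
    q <- gen$weights[fam] * fexp[fam]
    p[fam] <- (length(fam) / length(codons)) * q / sum(q)
  }
  p
}

#' Sample stop-free coding sequences from a species generator
#'
#' Each gene draws a target GC3 from the species distribution, a length from
#' `len_range`, and codons from the 59-codon degenerate universe with
#' probabilities combining the species' codon preferences and the
#' GC3-dependent expectation evaluated at the drawn GC3. The realized
#' third-position G/C fraction tracks the drawn value closely (exactly for
#' two- and four-fold families; the three- and six-fold families introduce a
#' deviation below 0.01 across the usable GC3 range). Sequences contain no
#' stop codons and always pass [codon_count_matrix()].
#'
#' @param gen a `species_generator`.
#' @param n number of genes.
#' @param seed integer seed.
#' @param prefix gene-id prefix (default the species name).
#' @return A [Biostrings::DNAStringSet]; per-gene target GC3 values are
#'   attached as attribute `"target_gc3"`.
#' @export
sample_genes <- function(gen, n, seed = 1L, prefix = gen$name) {
  stopifnot(inherits(gen, "species_generator"), n >= 1)
  gc <- .gcode()
  codons <- gc$profile_codons
  .with_seed(seed, {
    g_t <- pmin(pmax(stats::rnorm(n, gen$gc3_mean, gen$gc3_sd), 0.05), 0.95)
    len_choices <- seq(gen$len_range[1], gen$len_range[2])
    lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
    seqs <- vapply(seq_len(n), function(i) {
      p <- .codon_probs(gen, g_t[i])
      idx <- sample.int(length(codons), lens[i], replace = TRUE, prob = p)
      paste(codons[idx], collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("%s_%05d", prefix, seq_len(n))
    attr(out, "target_gc3") <- g_t
    out
  })
}

# ---------------------------------------------------------------------------
# planted genome

.place_interval <- function(glen, contigs, placed, condition, regions,
                            max_try = 2000L) {
  ctg_names <- names(contigs)
  for (try in seq_len(max_try)) {
    if (identical(condition, "inside")) {
      ridx <- sample.int(nrow(regions), 1L,
                         prob = regions$end - regions$start)
      ctg <- regions$contig[ridx]
      s <- floor(stats::runif(1, regions$start[ridx], regions$end[ridx]))
    } else {
      feas <- pmax(contigs - glen + 1, 0)
      ctg <- sample(ctg_names, 1L, prob = feas)
      s <- floor(stats::runif(1, 0, feas[ctg]))
    }
    e <- s + glen
    if (e > contigs[ctg]) next
    if (identical(condition, "outside") && !is.null(regions)) {
      r <- regions[regions$contig == ctg, , drop = FALSE]
      if (nrow(r) && any(s >= r$start & s < r$end)) next
    }
    pl <- placed[[ctg]]
    if (!is.null(pl) && any(s < pl[, 2] & e > pl[, 1])) next
    return(list(contig = ctg, start = s, end = e))
  }
  stop("genome too small to place all genes without overlap")
}

#' Plant a synthetic acceptor genome with known HGT structure
#'
#' Generates contigs, non-overlapping gene placements, coding sequences,
#' a homology table, a domain table and truth labels such that:
#' native genes come from the `acceptor` generator and have nematode
#' homologs; plain orphans, class I and class II genes come from the `donor`
#' generator and satisfy their defining homology rules exactly; retro genes
#' carry the [RETRO_DOMAINS] accessions with insect hits closer than
#' nematode hits (but less than 1000-fold, so they are not themselves class
#' II). Orphan, class I and class II genes are placed with start inside the
#' merged `flank`-bp neighborhoods of the retro genes with probability
#' `min(1, enrichment * f)` where `f` is the fraction of the genome covered
#' by those neighborhoods — so the expected colocalization fold enrichment
#' equals `enrichment`.
#'
#' @param n_native,n_orphan,n_class1,n_class2,n_retro gene counts per truth
#'   category.
#' @param enrichment target colocalization fold enrichment (>= 1).
#' @param contigs named numeric vector of contig lengths (bp).
#' @param seed integer seed.
#' @param flank neighborhood half-width in bp.
#' @param acceptor,donor `species_generator` objects; defaults are a
#'   nematode-like acceptor and an insect-like donor with analytic profiles
#'   about 1.1 apart.
#' @param n_conserved_both,n_conserved_one HGT candidates (class I then
#'   class II, in id order) planted as conserved in both / exactly one
#'   sister Pristionchus genome.
#' @param len_range gene length range in codons.
#' @param sequences if FALSE, skip coding-sequence simulation (gene
#'   placement, homology and domain tables only; the `sequences` element is
#'   NULL). Useful when only the colocalization geometry is of interest.
#' @return A `planted_genome`: list with `annotation` (gene_id, contig,
#'   start, end, strand, truth), `homology`, `domains`, `contigs`,
#'   `regions` (data.frame of the merged retro neighborhoods), `sequences`,
#'   `acceptor`, `donor`, `params`.
#' @export
plant_genome <- function(n_native = 600L, n_orphan = 150L, n_class1 = 25L,
                         n_class2 = 60L, n_retro = 15L, enrichment = 1,
                         contigs = stats::setNames(rep(2e6, 5),
                                                   paste0("contig", 1:5)),
                         seed = 1L, flank = 30000L,
                         acceptor = NULL, donor = NULL,
                         n_conserved_both = 0L, n_conserved_one = 0L,
                         len_range = c(100L, 400L), sequences = TRUE) {
  stopifnot(enrichment >= 1, n_retro >= 1)
  if (is.null(acceptor)) {
    acceptor <- make_species("acceptor", "nematode", gc3_mean = 0.42,
                             gc3_sd = 0.05, separation = 0.8, seed = 101L,
                             len_range = len_range)
  }
  if (is.null(donor)) {
    donor <- make_species("donor", "insect", gc3_mean = 0.55,
                          gc3_sd = 0.05, separation = 0.8, seed = 202L,
                          len_range = len_range)
  }
  cats <- c(native = n_native, orphan = n_orphan, class1 = n_class1,
            class2 = n_class2, retro = n_retro)
  ids <- unlist(lapply(names(cats), function(k) {
    if (cats[k] > 0) sprintf("%s_%04d", k, seq_len(cats[k])) else character(0)
  }))
  truth <- rep(names(cats), cats)

  if (sequences) {
    seqs <- c(
      sample_genes(acceptor, n_native, seed = seed + 11L, prefix = "native"),
      sample_genes(donor, n_orphan + n_class1 + n_class2 + n_retro,
                   seed = seed + 12L, prefix = "donorgene")
    )
    names(seqs) <- ids
    glen <- Biostrings::width(seqs)  # genomic length = CDS length, no introns
  } else {
    seqs <- NULL
    glen <- .with_seed(seed + 13L, {
      ch <- seq(len_range[1], len_range[2])
      3L * ch[sample.int(length(ch), length(ids), replace = TRUE)]
    })
  }

  ann <- .with_seed(seed, {
    placed <- list()
    rows <- vector("list", length(ids))
    # retro genes first: they define the neighborhoods
    retro_idx <- which(truth == "retro")
    for (i in retro_idx) {
      p <- .place_interval(glen[i], contigs, placed, "anywhere", NULL)
      placed[[p$contig]] <- rbind(placed[[p$contig]], c(p$start, p$end))
      rows[[i]] <- data.frame(gene_id = ids[i], contig = p$contig,
                              start = p$start, end = p$end,
                              stringsAsFactors = FALSE)
    }
    retro_df <- do.call(rbind, rows[retro_idx])
    regions <- regions_to_df(flank_regions(retro_df, contigs, flank))
    f <- sum(regions$end - regions$start) / sum(contigs)
    p_in <- min(1, enrichment * f)
    for (i in which(truth %in% c("orphan", "class1", "class2"))) {
      cond <- if (stats::runif(1) < p_in) "inside" else "outside"
      p <- .place_interval(glen[i], contigs, placed, cond, regions)
      placed[[p$contig]] <- rbind(placed[[p$contig]], c(p$start, p$end))
      rows[[i]] <- data.frame(gene_id = ids[i], contig = p$contig,
                              start = p$start, end = p$end,
                              stringsAsFactors = FALSE)
    }
    for (i in which(truth == "native")) {
      p <- .place_interval(glen[i], contigs, placed, "anywhere", NULL)
      placed[[p$contig]] <- rbind(placed[[p$contig]], c(p$start, p$end))
      rows[[i]] <- data.frame(gene_id = ids[i], contig = p$contig,
                              start = p$start, end = p$end,
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
    df$truth <- truth
    attr(df, "regions") <- regions
    df
  })
  regions <- attr(ann, "regions")
  attr(ann, "regions") <- NULL

  hom <- .with_seed(seed + 1L, {
    rows <- list()
    add <- function(gene, taxon, log10e) {
      data.frame(gene = gene, subject = paste0(taxon, "_subj"),
                 taxon = taxon, evalue = 10^log10e,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_along(ids)) {
      id <- ids[i]
      rows[[length(rows) + 1L]] <- switch(
        truth[i],
        native = {
          nl <- stats::runif(1, -100, -10)
          rbind(add(id, "nematode", nl),
                if (stats::runif(1) < 0.5)
                  add(id, "insect", nl + stats::runif(1, 1, 20)))
        },
        orphan = if (stats::runif(1) < 0.5)
          add(id, "insect", stats::runif(1, -2.5, 1)) else NULL,
        class1 = add(id, "insect", stats::runif(1, -50, -4)),
        class2 = {
          nl <- stats::runif(1, -30, -10)
          rbind(add(id, "nematode", nl),
                add(id, "insect", nl - stats::runif(1, 3, 30)))
        },
        retro = {
          il <- stats::runif(1, -60, -20)
          rbind(add(id, "insect", il),
                add(id, "nematode", il + stats::runif(1, 1, 2.9)))
        }
      )
    }
    candidates <- ids[truth %in% c("class1", "class2")]
    n_both <- min(n_conserved_both, length(candidates))
    n_one <- min(n_conserved_one, length(candidates) - n_both)
    if (n_both > 0) {
      both <- candidates[seq_len(n_both)]
      rows[[length(rows) + 1L]] <-
        rbind(add(both, "pristionchus_entomophagus",
                  stats::runif(n_both, -50, -4)),
              add(both, "pristionchus_maupasi",
                  stats::runif(n_both, -50, -4)))
    }
    if (n_one > 0) {
      one <- candidates[n_both + seq_len(n_one)]
      rows[[length(rows) + 1L]] <-
        add(one, "pristionchus_entomophagus", stats::runif(n_one, -50, -4))
    }
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })

  retro_ids <- ids[truth == "retro"]
  domains <- data.frame(
    gene = retro_ids,
    accession = rep(unname(RETRO_DOMAINS), length.out = length(retro_ids)),
    stringsAsFactors = FALSE
  )

  structure(list(
    annotation = ann, homology = hom, domains = domains,
    contigs = contigs, regions = regions, sequences = seqs,
    acceptor = acceptor, donor = donor,
    params = list(n_native = n_native, n_orphan = n_orphan,
                  n_class1 = n_class1, n_class2 = n_class2,
                  n_retro = n_retro, enrichment = enrichment,
                  flank = flank, seed = seed,
                  n_conserved_both = n_conserved_both,
                  n_conserved_one = n_conserved_one)
  ), class = "planted_genome")
}

# ---------------------------------------------------------------------------
# planted ESTs

# loop-based run scanner used only to certify constructed ESTs
.scan_runs <- function(s) {
  stops <- .gcode()$stop_codons
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  res <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    seqchr <- if (fr > 0) s else rc
    offset <- abs(fr) - 1L
    best <- 0L
    best_start <- NA_integer_
    run <- 0L
    run_start <- offset
    pos <- offset
    while (pos + 3L <= nchar(seqchr)) {
      cod <- substr(seqchr, pos + 1L, pos + 3L)
      if (cod %in% stops || grepl("[^ACGT]", cod)) {
        if (run > best) {
          best <- run
          best_start <- run_start
        }
        run <- 0L
        run_start <- pos + 3L
      } else {
        run <- run + 1L
      }
      pos <- pos + 3L
    }
    if (run > best) {
      best <- run
      best_start <- run_start
    }
    res[[as.character(fr)]] <- c(frame = fr, longest = 3L * best,
                                 start = best_start)
  }
  do.call(rbind, res)
}

# stop-rich filler: each codon is a stop with probability 0.5
.stop_soup <- function(n_codons) {
  gc <- .gcode()
  pool <- ifelse(stats::runif(n_codons) < 0.5,
                 sample(gc$stop_codons, n_codons, replace = TRUE),
                 sample(names(gc$code), n_codons, replace = TRUE))
  paste(pool, collapse = "")
}

# stop-free codon stretch salted so every other reading frame (both strands)
# hits a stop at least once per ~90 bp
.stopfree_salted <- function(n_codons) {
  gc <- .gcode()
  pairs <- c("CTAAAA", "CCTAAA", "TTAGCC", "CTTACC", "CCTTAC")
  cods <- character(0)
  pi <- 0L
  while (length(cods) < n_codons) {
    cods <- c(cods, sample(names(gc$code), 4L, replace = TRUE))
    pi <- pi %% length(pairs) + 1L
    p <- pairs[pi]
    cods <- c(cods, substr(p, 1, 3), substr(p, 4, 6))
  }
  paste(cods[seq_len(n_codons)], collapse = "")
}

#' Plant EST sequences with known CDS truth
#'
#' Each EST carries exactly one maximal stop-free run (the planted ORF) in a
#' random frame; all other reading frames are salted with stop codons so
#' their longest runs stay at or below 120 bp, except that a fraction of
#' ESTs receives a decoy run of 153-279 bp in another frame, which makes the
#' six-frame rule reject them. ESTs whose planted ORF is shorter than
#' `min_len` are likewise rejected by construction. Constructions are
#' certified with an internal codon-by-codon scan and redrawn in the rare
#' case a random flank violates the salting bound.
#'
#' @param n number of ESTs.
#' @param orf_len_range planted ORF length range in bp (rounded down to
#'   codon multiples; must lie within \[150, 3000\]).
#' @param decoy_frac fraction of ESTs given a decoy run (truth: rejected).
#' @param seed integer seed.
#' @param min_len,second_max the six-frame rule thresholds used to label
#'   truth.
#' @return list with `ests` ([Biostrings::DNAStringSet]) and `truth`
#'   (data.frame est_id, frame, start, end, longest_len,
#'   second_longest_len, accepted) in [select_cds()] coordinates.
#' @export
plant_ests <- function(n, orf_len_range = c(240L, 600L), decoy_frac = 0.25,
                       seed = 1L, min_len = 300L, second_max = 150L) {
  stopifnot(orf_len_range[1] >= 150, orf_len_range[2] <= 3000)
  .with_seed(seed, {
    ests <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        cod_range <- seq(orf_len_range[1] %/% 3L, orf_len_range[2] %/% 3L)
        orf_cod <- cod_range[sample.int(length(cod_range), 1L)]
        orf_bp <- 3L * orf_cod
        offset <- sample(0:2, 1L)
        flip <- stats::runif(1) < 0.5
        decoy <- stats::runif(1) < decoy_frac
        decoy_bp <- 0L
        f1_cod <- sample(15:40, 1L)
        flank1 <- paste0(strrep("A", offset), .stop_soup(f1_cod))
        orf_start <- nchar(flank1) + 3L
        body <- paste0(flank1, "TAA", .stopfree_salted(orf_cod), "TAA")
        if (decoy) {
          max_decoy <- min(279L, orf_bp - 21L)
          if (max_decoy >= 153L) {
            dc_range <- seq(51L, max_decoy %/% 3L)
            decoy_cod <- dc_range[sample.int(length(dc_range), 1L)]
            decoy_bp <- 3L * decoy_cod
            soup_a <- .stop_soup(sample(8:20, 1L))
            d_off <- sample(setdiff(0:2, offset), 1L)
            pad <- (d_off - (nchar(body) + nchar(soup_a))) %% 3L
            body <- paste0(body, soup_a, strrep("A", pad), "TAA",
                           .stopfree_salted(decoy_cod), "TAA")
          } else {
            decoy <- FALSE
          }
        }
        body <- paste0(body, .stop_soup(sample(10:30, 1L)))
        # certify the construction
        runs <- .scan_runs(body)
        planted_row <- runs[runs[, "frame"] == offset + 1L, , drop = FALSE]
        others <- runs[runs[, "frame"] != offset + 1L, "longest"]
        base_ok <- planted_row[1, "longest"] == orf_bp &&
          planted_row[1, "start"] == orf_start
        ok <- if (decoy_bp > 0L) {
          base_ok && max(others) == decoy_bp &&
            sort(others, decreasing = TRUE)[2] <= 120L
        } else {
          base_ok && max(others) <= 120L
        }
        if (!ok) next
        second <- max(others)
        est <- if (flip) {
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(body)))
        } else body
        frame <- if (flip) -(offset + 1L) else offset + 1L
        truth[[i]] <- data.frame(
          est_id = sprintf("est_%05d", i),
          frame = frame,
          start = orf_start,
          end = orf_start + orf_bp,
          longest_len = orf_bp,
          second_longest_len = second,
          accepted = orf_bp >= min_len && second <= second_max,
          stringsAsFactors = FALSE
        )
        ests[i] <- est
        break
      }
    }
    out <- Biostrings::DNAStringSet(ests)
    names(out) <- sprintf("est_%05d", seq_len(n))
    list(ests = out, truth = do.call(rbind, truth))
  })
}

# ---------------------------------------------------------------------------
# serialization

#' Write a planted genome to disk as plain-text files
#'
#' Emits CDS FASTA, a GFF3 of gene models (truth category as attribute),
#' homology and domain TSVs, a contigs TSV, and a JSON truth file.
#'
#' @param pg a `planted_genome`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_planted_genome <- function(pg, dir) {
  stopifnot(inherits(pg, "planted_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genes.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    homology = file.path(dir, "homology.tsv"),
    domains = file.path(dir, "domains.tsv"),
    contigs = file.path(dir, "contigs.tsv"),
    truth = file.path(dir, "truth.json")
  )
  Biostrings::writeXStringSet(pg$sequences, paths["fasta"])
  write_annotation_gff3(pg$annotation, pg$contigs, paths["gff3"])
  utils::write.table(pg$homology, paths["homology"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pg$domains, paths["domains"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(contig = names(pg$contigs), length = unname(pg$contigs)),
    paths["contigs"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(params = pg$params,
         truth = pg$annotation[, c("gene_id", "truth")]),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' GFF3 input/output for gene annotations
#'
#' Internally coordinates are 0-based half-open; GFF3 is 1-based inclusive.
#' Requires the rtracklayer package.
#'
#' @param annotation data.frame with gene_id, contig, start, end, strand and
#'   optionally truth.
#' @param contigs named numeric vector of contig lengths.
#' @param path file path.
#' @export
write_annotation_gff3 <- function(annotation, contigs, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 output")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(start = annotation$start + 1,
                              end = annotation$end),
    strand = annotation$strand,
    type = "gene",
    ID = annotation$gene_id
  )
  if (!is.null(annotation$truth)) gr$truth <- annotation$truth
  GenomeInfoDb::seqlengths(gr) <- contigs[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @return `read_annotation_gff3()` returns the annotation data.frame
#'   (0-based half-open coordinates).
#' @export
read_annotation_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 input")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    gene_id = gr$ID,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$truth)) df$truth <- gr$truth
  df[order(df$contig, df$start, df$gene_id), , drop = FALSE]
}
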