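test_that("codon extraction counts in-frame codons and trims the stop", {
  cc <- extract_codons("ATGGAAGAG")
  expect_equal(unname(cc$counts[c("ATG", "GAA", "GAG")]), c(1L, 1L, 1L))
  expect_equal(cc$n_codons, 3L)

  cc <- extract_codons("ATGTAA")
  expect_equal(unname(cc$counts["ATG"]), 1L)
  expect_equal(cc$n_codons, 1L)

  expect_error(extract_codons("ATGGA"), "divisible by 3")
  expect_error(extract_codons("ATGTAAGAA"), "internal stop")
  expect_error(extract_codons("ATGNNNGAA"), "non-A/C/G/T")
})

test_that("codon counts agree with a sliding-window oracle", {
  set.seed(11)
  s <- random_cds(300)
  cc <- extract_codons(s)
  expect_equal(cc$n_codons, 300L)
  ora <- oracle_count_codons(s)
  for (cod in names(ora)) {
    expect_equal(unname(cc$counts[cod]), unname(ora[cod]))
  }
  expect_equal(sum(cc$counts), sum(ora))
})

test_that("GC3 is the third-position G/C fraction", {
  expect_equal(unname(gc3(extract_codons("ATGGAAGAG"))), 2 / 3)
  expect_equal(unname(gc3(extract_codons("GAAGATCTT"))), 0)
  gen <- make_species("s", "nematode", gc3_mean = 0.6, gc3_sd = 0,
                      separation = 0, len_range = c(5000L, 5000L))
  g <- sample_genes(gen, 2, seed = 4)
  expect_true(all(abs(gc3(codon_count_matrix(g)) - 0.6) < 0.02))
})

test_that("expected codon frequencies follow the per-nucleotide GC model", {
  gcode <- genetic_code()
  # uniform at GC3 = 0.5
  f <- expected_codon_freq(0.5)$f_exp[1, ]
  sizes <- lengths(gcode$families)[gcode$family_of]
  expect_equal(unname(f), unname(1 / sizes), tolerance = 1e-12)
  # two-fold Glu family at GC3 = 0.7
  f7 <- expected_codon_freq(0.7)$f_exp[1, ]
  expect_equal(unname(f7["GAG"]), 0.7, tolerance = 1e-12)
  expect_equal(unname(f7["GAA"]), 0.3, tolerance = 1e-12)
  # per-family normalization across a GC3 grid
  for (g in seq(0.01, 0.99, by = 0.07)) {
    fe <- expected_codon_freq(g)$f_exp[1, ]
    for (fam in gcode$families) {
      expect_equal(sum(fe[fam]), 1, tolerance = 1e-12)
    }
  }
  # clamping keeps frequencies positive at the boundaries
  expect_true(all(expected_codon_freq(0)$f_exp > 0))
  expect_true(all(expected_codon_freq(1)$f_exp > 0))
})

test_that("RSCU profiles match hand evaluation", {
  cc <- extract_codons("GAAGAGGAGGAG")  # GAA:1 GAG:3
  p <- rscu_profile(cc, gc3 = 0.75, normalized = TRUE)
  expect_equal(unname(p["GAG"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(p["GAA"]), 1.0, tolerance = 1e-12)
  p2 <- rscu_profile(cc, normalized = FALSE)
  expect_equal(unname(p2["GAG"]), 1.5, tolerance = 1e-12)
  expect_equal(unname(p2["GAA"]), 0.5, tolerance = 1e-12)
  # absent families imputed to the neutral value
  expect_equal(unname(p["TTT"]), 1)
})

test_that("GC-normalized equals classic RSCU at GC3 = 0.5", {
  set.seed(21)
  m <- codon_count_matrix(vapply(1:5, function(i) random_cds(200),
                                 character(1)))
  pn <- rscu_matrix(m, gc3 = rep(0.5, 5), normalized = TRUE)
  pc <- rscu_matrix(m, gc3 = rep(0.5, 5), normalized = FALSE)
  expect_equal(unclass(pn)[, ], unclass(pc)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("genomewide profile is the unweighted componentwise mean", {
  a <- profile_from(rep(0, 59))
  b <- profile_from(rep(2, 59))
  expect_equal(as.numeric(genomewide_profile(list(a, a))), rep(0, 59))
  expect_equal(as.numeric(genomewide_profile(list(a, b))), rep(1, 59))
  expect_error(genomewide_profile(list()), "no profiles")
  c_ <- profile_from(rep(1, 59), normalized = FALSE)
  expect_error(genomewide_profile(list(a, c_)), "mixed normalization")
})

test_that("empirical mean profile converges to the generator's analytic one", {
  # long genes: per-gene GC3 estimation noise (which biases the ratio
  # statistic for short genes) is negligible in this regime
  gen <- make_species("conv", "insect", gc3_mean = 0.5, gc3_sd = 0.04,
                      separation = 0.6, seed = 7,
                      len_range = c(1000L, 2000L))
  m <- codon_count_matrix(sample_genes(gen, 2000, seed = 8))
  prof <- genomewide_profile(rscu_matrix(m))
  expect_lt(max(abs(prof - analytic_profile(gen))), 0.05)
})

test_that("deviation scores are exact Euclidean/absolute measures", {
  set.seed(31)
  m <- codon_count_matrix(vapply(1:20, function(i) random_cds(150),
                                 character(1)))
  ref <- genome_reference(m)
  dev <- deviation_scores(m, ref)
  # identity: a reference built from a single gene scores zero on itself
  one <- m[1, , drop = FALSE]
  ref1 <- genome_reference(one)
  dev1 <- deviation_scores(one, ref1)
  expect_equal(dev1$d_rscu, 0, tolerance = 1e-12)
  expect_equal(dev1$d_rscu_gc, 0, tolerance = 1e-12)
  expect_equal(dev1$d_gc3, 0, tolerance = 1e-12)
  # random pair vs naive loop
  g <- gc3(m)
  pg <- rscu_matrix(m, g, normalized = TRUE)
  for (i in c(1, 7, 20)) {
    expect_equal(dev$d_rscu_gc[i],
                 oracle_euclid(pg[i, ], as.numeric(ref$profile_gc)),
                 tolerance = 1e-12)
  }
  # single differing component
  x <- profile_from(rep(1, 59))
  y <- profile_from(c(1.7, rep(1, 58)))
  expect_equal(profile_distance(x, y), 0.7, tolerance = 1e-12)
  # deviations invariant under gene reordering
  dev_r <- deviation_scores(m[20:1, ], ref)
  expect_equal(dev_r$d_rscu_gc[20], dev$d_rscu_gc[1])
})

test_that("pearson correlation validates input and matches the formula", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_error(pearson_correlation(x, rep(1, 5)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  set.seed(41)
  a <- rnorm(10); b <- rnorm(10)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_correlation(a, b), manual, tolerance = 1e-12)
})

test_that("GC normalization decorrelates codon-usage deviation from GC3", {
  # genes from one species whose only systematic variation is GC3-driven
  gen <- make_species("wide", "nematode", gc3_mean = 0.5, gc3_sd = 0.12,
                      separation = 0, seed = 5)
  m <- codon_count_matrix(sample_genes(gen, 400, seed = 6))
  ref <- genome_reference(m)
  dev <- deviation_scores(m, ref)
  r_classic <- pearson_correlation(dev$d_rscu, dev$d_gc3)
  r_gc <- pearson_correlation(dev$d_rscu_gc, dev$d_gc3)
  expect_gt(r_classic, r_gc)
})

test_that("FASTA reading and deviation TSV round-trip", {
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">geneA some description", "ATGGAAGAGTAA",
               ">geneB", "ATGCTTCTCCTG"), tmp)
  seqs <- read_cds_fasta(tmp)
  expect_equal(names(seqs), c("geneA", "geneB"))
  m <- codon_count_matrix(seqs)
  expect_equal(unname(rowSums(m)), c(3, 4))
  dev <- deviation_scores(m, genome_reference(m, min_codons = 1L))
  out <- tempfile(fileext = ".tsv")
  write_deviation_tsv(dev, out)
  back <- read.delim(out)
  expect_equal(back$gene_id, dev$gene_id)
  expect_equal(back$d_rscu_gc, dev$d_rscu_gc, tolerance = 1e-9)
})
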