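ctg <- c(chrA = 200000, chrB = 150000)

test_that("flank regions extend, clip and merge correctly", {
  g <- data.frame(contig = "chrA", start = 50000, end = 51000)
  r <- regions_to_df(flank_regions(g, ctg, 30000))
  expect_equal(r$start, 20000)
  expect_equal(r$end, 81000)
  expect_equal(r$width, 61000)

  # two genes 10 kb apart merge into one region
  g2 <- data.frame(contig = "chrA", start = c(50000, 61000),
                   end = c(51000, 62000))
  r2 <- regions_to_df(flank_regions(g2, ctg, 30000))
  expect_equal(nrow(r2), 1)
  expect_equal(r2$width, 72000)

  # clipping at contig bounds
  g3 <- data.frame(contig = "chrA", start = 1000, end = 2000)
  r3 <- regions_to_df(flank_regions(g3, ctg, 30000))
  expect_equal(r3$start, 0)

  expect_error(flank_regions(data.frame(contig = "nope", start = 1,
                                        end = 10), ctg), "unknown contig")
  expect_error(flank_regions(data.frame(contig = "chrA", start = -5,
                                        end = 10), ctg), "outside")
})

test_that("region merging is idempotent and order-invariant", {
  set.seed(3)
  g <- data.frame(contig = sample(names(ctg), 20, replace = TRUE),
                  start = sample(100000, 20))
  g$end <- g$start + sample(500:3000, 20)
  a <- regions_to_df(flank_regions(g, ctg, 5000))
  b <- regions_to_df(flank_regions(g[sample(20), ], ctg, 5000))
  expect_equal(a, b)
  # merging the merged regions changes nothing
  c_ <- regions_to_df(flank_regions(a[, c("contig", "start", "end")],
                                    ctg, 0))
  expect_equal(c_$start, a$start)
  expect_equal(c_$end, a$end)
  expect_equal(sum(a$width), sum(a$end - a$start))
})

test_that("retro reference set requires domains plus closer insect homology", {
  ann <- data.frame(gene_id = c("r1", "r2", "r3", "x1"),
                    contig = "chrA", start = c(1, 100, 200, 300) * 100,
                    end = c(1, 100, 200, 300) * 100 + 500,
                    strand = "+")
  dom <- data.frame(gene = c("r1", "r2", "r3"),
                    accession = c("PF00078.20", "PF03372.16", "PF03732.10"))
  hom <- data.frame(gene = c("r1", "r1", "r2", "r2"),
                    subject = "s",
                    taxon = c("insect", "nematode", "insect", "nematode"),
                    evalue = c(1e-30, 1e-10, 1e-10, 1e-30))
  expect_warning(res <- reference_retro_genes(ann, dom, hom),
                 "lack homology rows")
  expect_equal(res, "r1")   # r2 nematode-closer, r3 no homology rows

  pg <- plant_genome(n_native = 40, n_orphan = 10, n_class1 = 5,
                     n_class2 = 10, n_retro = 15, seed = 12,
                     sequences = FALSE)
  got <- reference_retro_genes(pg$annotation, pg$domains, pg$homology)
  expect_setequal(got,
                  pg$annotation$gene_id[pg$annotation$truth == "retro"])
})

test_that("bounded-locus scan enforces span, strand and containment", {
  ann <- data.frame(
    gene_id = c("endo1", "rt1", paste0("mid", 1:8), "rt2", "endo3", "rt3"),
    contig = c(rep("chrA", 10), "chrA", "chrB", "chrB"),
    start = c(10000, 48000, seq(12000, 40000, length.out = 8),
              95000, 10000, 52000),
    end = c(11000, 50000, seq(12500, 40500, length.out = 8),
            96000, 11000, 53000),
    strand = c(rep("+", 11), "+", "-")
  )
  loci <- scan_bounded_loci(ann, endo_genes = c("endo1", "endo3"),
                            rt_genes = c("rt1", "rt2", "rt3"),
                            max_span = 40000)
  expect_equal(nrow(loci), 1)   # endo1-rt1; rt2 too far, rt3 wrong strand
  expect_equal(loci$endo_gene, "endo1")
  expect_equal(loci$rt_gene, "rt1")
  expect_equal(loci$n_embedded, 8)
  expect_equal(loci$span, 40000)

  # span one bp over the limit: no locus
  ann2 <- ann
  ann2$end[ann2$gene_id == "rt1"] <- 50001
  expect_equal(nrow(scan_bounded_loci(ann2, "endo1", "rt1", 40000)), 0)

  # opposite strands: no locus
  ann3 <- ann
  ann3$strand[ann3$gene_id == "rt1"] <- "-"
  expect_equal(nrow(scan_bounded_loci(ann3, "endo1", "rt1", 40000)), 0)

  # row order must not matter
  loci_r <- scan_bounded_loci(ann[sample(nrow(ann)), ],
                              c("endo1", "endo3"), c("rt1", "rt2", "rt3"),
                              40000)
  expect_equal(loci_r, loci)
})

test_that("permutation test recovers extreme planted enrichment", {
  regions <- data.frame(contig = "chrA",
                        start = c(0, 100000), end = c(10000, 110000))
  # all targets inside regions covering 10% of a 200-kb genome
  targets <- data.frame(contig = "chrA",
                        start = c(500, 5000, 9000, 100500, 105000, 109000))
  res <- permutation_enrichment(regions, targets, c(chrA = 200000),
                                n_iter = 300, seed = 5)
  expect_equal(res$observed, 6)
  expect_equal(res$p.value, 1 / 301)
  expect_gt(res$fold, 5)   # analytic expectation: 1 / 0.1 = 10, noisy mean
  expect_lt(res$fold, 20)
})

test_that("permutation test is calibrated under uniform placement", {
  set.seed(8)
  contigs <- c(c1 = 1e6, c2 = 1e6)
  anchors <- data.frame(contig = sample(names(contigs), 20, replace = TRUE),
                        start = sample(9e5, 20))
  anchors$end <- anchors$start + 1000
  regions <- regions_to_df(flank_regions(anchors, contigs, 15000))
  targets <- data.frame(contig = sample(names(contigs), 600, replace = TRUE),
                        start = sample(1e6 - 1000, 600))
  res <- permutation_enrichment(regions, targets, contigs,
                                n_iter = 400, seed = 21)
  expect_lt(abs(res$fold - 1), 0.15)
  expect_gt(res$p.value, 0.05)
  # mean sampled count close to the analytic span fraction
  expect_lt(abs(res$sampled_mean -
                  600 * res$region_span / res$genome_span),
            3 * sqrt(res$sampled_mean))
  # add-one correction: p can never be zero
  expect_gt(res$p.value, 0)
})

test_that("infeasible sampling configurations abort with a diagnostic", {
  regions <- data.frame(contig = "chrA", start = 0, end = 150000)
  targets <- data.frame(contig = "chrA", start = 1:5 * 1000)
  expect_error(
    permutation_enrichment(regions, targets, c(chrA = 200000),
                           n_iter = 10, seed = 1),
    "more than half")
})
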