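make_refs <- function(values_list, names, taxa) {
  lapply(seq_along(values_list), function(i) {
    species_profile(names[i], taxa[i], profile_from(values_list[[i]]))
  })
}

test_that("nearest-neighbor assignment is exact, tie-broken, order-invariant", {
  refA <- rep(1, 59)
  refB <- c(rep(1.5, 10), rep(1, 49))
  refs <- make_refs(list(refA, refB), c("alpha", "beta"),
                    c("nematode", "insect"))
  # identity
  asg <- assign_nearest(profile_from(refA), refs)
  expect_equal(asg$species, "alpha")
  expect_equal(asg$distance, 0)
  # equidistant tie goes to the lexicographically first species
  mid <- (refA + refB) / 2
  tie <- assign_nearest(profile_from(mid), refs)
  expect_equal(tie$species, "alpha")
  # reference order must not matter
  tie2 <- assign_nearest(profile_from(mid), rev(refs))
  expect_equal(tie2$species, "alpha")
  # distances attribute matches a direct computation
  d <- attr(asg, "distances")
  expect_equal(unname(d[1, "beta"]),
               oracle_euclid(refA, refB), tolerance = 1e-12)
  expect_error(assign_nearest(profile_from(refA), list()), "empty")
})

test_that("genes from well-separated species are recovered", {
  sp <- lapply(1:4, function(i) {
    make_species(paste0("sp", i), TAXON_GROUPS[i],
                 gc3_mean = c(0.35, 0.45, 0.55, 0.65)[i],
                 separation = 1.6, seed = 100 + i,
                 len_range = c(150L, 500L))
  })
  refs <- lapply(sp, function(g) {
    species_profile(g$name, g$taxon, analytic_profile(g))
  })
  asg <- do.call(rbind, lapply(sp, function(g) {
    m <- codon_count_matrix(sample_genes(g, 150, seed = g$seed + 1))
    cbind(assign_nearest(rscu_matrix(m), refs), truth = g$name)
  }))
  expect_gt(mean(asg$species == asg$truth), 0.9)
})

test_that("taxon distribution sums to one and recovers planted fractions", {
  asg <- data.frame(gene_id = c("a", "b"), taxon = c("nematode", "nematode"))
  fr <- taxon_distribution(asg)
  expect_equal(unname(fr["nematode"]), 1)
  expect_equal(sum(fr), 1)
  asg2 <- data.frame(gene_id = letters[1:4],
                     taxon = c("insect", "insect", "fungi", "fungi"))
  fr2 <- taxon_distribution(asg2)
  expect_equal(unname(fr2[c("insect", "fungi")]), c(0.5, 0.5))

  # acceptor genome with 5% planted donor-profile genes
  acc <- make_species("acc", "nematode", gc3_mean = 0.45, separation = 1.4,
                      seed = 31, len_range = c(150L, 500L))
  don <- make_species("don", "insect", gc3_mean = 0.55, separation = 1.4,
                      seed = 32, len_range = c(150L, 500L))
  m <- codon_count_matrix(c(sample_genes(acc, 380, seed = 33),
                            sample_genes(don, 20, seed = 34)))
  refs <- list(species_profile("acc", "nematode", analytic_profile(acc)),
               species_profile("don", "insect", analytic_profile(don)))
  fr3 <- taxon_distribution(assign_nearest(rscu_matrix(m), refs))
  expect_lt(abs(fr3["insect"] - 0.05), 0.02)
})

test_that("cross-validation holds out validation genes and is calibrated", {
  # two species from identical generator settings are indistinguishable:
  # accuracy must sit at the 50% chance level
  twin <- function(nm) {
    g <- make_species(nm, "nematode", gc3_mean = 0.5, separation = 0.8,
                      seed = 55, len_range = c(150L, 400L))
    g
  }
  sets <- list(
    twinA = list(taxon = "nematode",
                 counts = codon_count_matrix(
                   sample_genes(twin("twinA"), 220, seed = 61))),
    twinB = list(taxon = "nematode",
                 counts = codon_count_matrix(
                   sample_genes(twin("twinB"), 220, seed = 62)))
  )
  cv <- crossvalidate(sets, n_val = 80L, reps = 5L, seed = 9L)
  expect_lt(abs(cv$species_accuracy["mean"] - 0.5), 0.05)
  # confusion rows sum to 100 for observed taxa
  active <- rowSums(cv$confusion_mean) > 0
  expect_equal(unname(rowSums(cv$confusion_mean)[active]),
               rep(100, sum(active)))
  # species with too few genes are dropped with a warning
  sets$tiny <- list(taxon = "fungi",
                    counts = sets$twinA$counts[1:50, ])
  expect_warning(crossvalidate(sets, n_val = 80L, reps = 2L, seed = 9L),
                 "excluding species")
})

test_that("relative distances are a unit partition and detect planted donors", {
  gcode <- genetic_code()
  p <- profile_from(rep(1, 59))
  r1 <- profile_from(c(rep(1.2, 10), rep(1, 49)))
  r2 <- profile_from(c(rep(1, 49), rep(1.2, 10)))
  r3 <- profile_from(c(rep(0.8, 10), rep(1, 49)))
  rd <- relative_distance(p, r1, r2, r3)
  expect_equal(rd$rel_self + rd$rel_fungal + rd$rel_insect, 1,
               tolerance = 1e-12)
  # equidistant from all three
  expect_equal(unname(unlist(rd[1, c("rel_self", "rel_fungal",
                                     "rel_insect")])),
               rep(1 / 3, 3), tolerance = 1e-12)
  # identical to the insect reference
  rd2 <- relative_distance(r3, r1, r2, r3)
  expect_equal(rd2$rel_insect, 0)
  expect_error(relative_distance(p, p, p, p), "equidistant at zero")

  # planted insect-donor genes sit closer to the insect reference
  acc <- make_species("acc", "nematode", gc3_mean = 0.45, separation = 1.2,
                      seed = 71, len_range = c(150L, 400L))
  don <- make_species("don", "insect", gc3_mean = 0.55, separation = 1.2,
                      seed = 72, len_range = c(150L, 400L))
  fun <- make_species("fun", "fungi", gc3_mean = 0.5, separation = 1.2,
                      seed = 73, len_range = c(150L, 400L))
  m_nat <- rscu_matrix(codon_count_matrix(sample_genes(acc, 200, seed = 74)))
  m_hgt <- rscu_matrix(codon_count_matrix(sample_genes(don, 200, seed = 75)))
  rd_nat <- relative_distance(m_nat, analytic_profile(acc),
                              analytic_profile(fun), analytic_profile(don))
  rd_hgt <- relative_distance(m_hgt, analytic_profile(acc),
                              analytic_profile(fun), analytic_profile(don))
  rs <- ranksum_compare(rd_hgt$rel_insect, rd_nat$rel_insect,
                        alternative = "less")
  expect_lt(rs$p.value, 0.01)
})

test_that("reference profiles survive a TSV round trip", {
  refs <- list(
    species_profile("zeta", "plant", profile_from(seq(0.5, 1.5,
                                                      length.out = 59))),
    species_profile("eta", "bacteria", profile_from(rep(1, 59)))
  )
  tmp <- tempfile(fileext = ".tsv")
  write_reference_tsv(refs, tmp)
  back <- read_reference_tsv(tmp)
  expect_equal(vapply(back, `[[`, character(1), "species"),
               c("zeta", "eta"))
  expect_equal(as.numeric(back[[1]]$profile),
               as.numeric(refs[[1]]$profile), tolerance = 1e-9)
  expect_equal(back[[2]]$taxon, "bacteria")
})
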