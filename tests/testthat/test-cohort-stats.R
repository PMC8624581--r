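# Genotype counting, allele frequencies, stratified tables, relatives

test_that("genotype counting reproduces the packaged cohort tables", {
  ft <- fixture_tables()
  aht <- ft$cohorts[ft$cohorts$stratum == "AHT", ]
  expect_equal(unlist(aht[, c("n_hom_alt", "n_het", "n_hom_ref")],
                      use.names = FALSE), c(5L, 11L, 75L))
  expect_equal(aht$total, 91L)
  # summed across the five cohorts: the whole case-breed population
  expect_equal(colSums(ft$cohorts[, c("n_hom_alt", "n_het", "n_hom_ref")]),
               c(n_hom_alt = 7, n_het = 17, n_hom_ref = 481))
  expect_equal(sum(ft$cohorts$total), 505L)
})

test_that("count_genotypes handles empty input and missing calls", {
  e <- count_genotypes(integer(0))
  expect_equal(c(e$n_hom_alt, e$n_het, e$n_hom_ref, e$total), rep(0L, 4))
  c_ <- count_genotypes(c(2L, 1L, 0L, NA, NA))
  expect_equal(c_$total, 3L)      # missing excluded from the denominator
  expect_equal(c_$n_missing, 2L)
})

test_that("allele frequency matches a per-allele tally and the display rounding", {
  expect_equal(round_half_up(allele_frequency(genotype_counts(7, 17, 481))), 0.031)
  expect_equal(round_half_up(allele_frequency(genotype_counts(4, 13, 481))), 0.021)
  expect_equal(allele_frequency(genotype_counts(0, 0, 858)), 0)
  expect_equal(allele_frequency(genotype_counts(1, 0, 0)), 1)
  expect_error(allele_frequency(genotype_counts(0, 0, 0)), "undefined-frequency")
  # per-allele oracle on random counts
  set.seed(21)
  for (rep in 1:20) {
    n <- c(sample(0:20, 2), sample(1:50, 1))
    alleles <- c(rep(1, 2 * n[1]), rep(c(1, 0), n[2]), rep(0, 2 * n[3]))
    af <- allele_frequency(genotype_counts(n[1], n[2], n[3]))
    expect_equal(af, mean(alleles))
    expect_gte(af, 0); expect_lte(af, 1)
  }
})

test_that("rounding is half-up, not banker's", {
  expect_equal(round_half_up(0.0305, 3), 0.031)
  expect_equal(round_half_up(0.0215, 3), 0.022)
})

test_that("stratified tables preserve row sums and collapse to plain counts", {
  ft <- fixture_tables()
  ph <- ft$phenotypes
  expect_equal(unlist(ph[ph$stratum == "case", c("n_hom_alt", "n_het", "n_hom_ref")],
                      use.names = FALSE), c(4L, 0L, 10L))
  expect_equal(unlist(ph[ph$stratum == "control", c("n_hom_alt", "n_het", "n_hom_ref")],
                      use.names = FALSE), c(2L, 11L, 29L))
  expect_equal(unlist(ph[ph$stratum == "unknown", c("n_hom_alt", "n_het", "n_hom_ref")],
                      use.names = FALSE), c(1L, 6L, 442L))
  # single stratum equals count_genotypes; randomized labels keep row sums
  set.seed(31)
  gt <- sample(c(0:2, NA), 200, replace = TRUE)
  one <- stratified_table(rep("all", 200), gt)
  c_ <- count_genotypes(gt)
  expect_equal(one$n_hom_alt, c_$n_hom_alt)
  expect_equal(one$total, c_$total)
  rnd <- stratified_table(sample(letters[1:4], 200, replace = TRUE), gt)
  expect_equal(sum(rnd$total), c_$total)
  expect_equal(sum(rnd$n_missing), c_$n_missing)
})

test_that("relative enumeration covers siblings but not unrelated founders", {
  fp <- fixture_population()
  rel <- relatives_within_generations(fp$pedigree, "SS1", 3)
  expect_true(all(c("SS2", "SS3", "REL1", "REL4") %in% rel))
  expect_false("SS1" %in% rel) # proband excluded from the returned set
  # two founders with no shared ancestor are unrelated
  ped <- pedigree(c("A", "B"), c("0", "0"), c("0", "0"))
  expect_length(relatives_within_generations(ped, "A", 3), 0L)
  expect_error(relatives_within_generations(ped, "ZZ", 3), "unknown-individual")
})

test_that("relatedness respects the generation depth on a hand-drawn pedigree", {
  # Q shares only a great-great-grandsire (4 links) with P: related at g=4, not g=3
  ped <- pedigree(
    id   = c("P", "PA", "PG", "PGG", "Q", "QA", "QG", "QGG"),
    sire = c("PA", "PG", "PGG", "TOP", "QA", "QG", "QGG", "TOP"),
    dam  = rep("0", 8)
  )
  expect_false("Q" %in% relatives_within_generations(ped, "P", 3))
  expect_true("Q" %in% relatives_within_generations(ped, "P", 4))
  # direct ancestors within g links are included
  expect_true(all(c("PA", "PG", "PGG") %in% relatives_within_generations(ped, "P", 3)))
  expect_false("TOP" %in% relatives_within_generations(ped, "P", 3))
})
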