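# Recessive / X-linked segregation filters and the known-variant screen

toy_set <- function(geno_rows, chroms = NULL, samples = c("case", "c1", "c2")) {
  n <- nrow(geno_rows)
  if (is.null(chroms)) chroms <- rep("1", n)
  variant_set(
    data.frame(chrom = chroms, pos = seq_len(n) * 10L, ref = "A", alt = "T",
               stringsAsFactors = FALSE),
    matrix(as.integer(geno_rows), nrow = n, dimnames = list(NULL, samples))
  )
}

test_that("recessive retention: case hom-alt kept unless any control is hom-alt", {
  vs <- toy_set(rbind(
    c(2, 1, 0), # carriers among controls -> kept
    c(1, 0, 0), # case het -> removed
    c(2, 2, 0)  # a control homozygote -> removed
  ))
  out <- filter_recessive(vs, "case", c("c1", "c2"))
  expect_equal(vs_keys(out), vs_keys(vs)[1])
})

test_that("recessive filter agrees with exhaustive enumeration of a 1-case/2-control toy", {
  # all 3^3 genotype assignments, checked against an independent per-variant loop
  grid <- expand.grid(case = 0:2, c1 = 0:2, c2 = 0:2)
  vs <- toy_set(as.matrix(grid))
  got <- vs_keys(filter_recessive(vs, "case", c("c1", "c2")))
  expect_equal(got, brute_recessive_keys(vs, "case", c("c1", "c2")))
  # and the keep-set is exactly {case==2 and no control==2}, 4 of 27 rows
  expect_length(got, 4L)
})

test_that("missing genotypes never satisfy a predicate but only veto on request", {
  vs <- toy_set(rbind(
    c(NA, 0, 0), # missing case fails the case condition
    c(2, NA, 0)  # missing control: kept by default, removed with missing_vetoes
  ))
  expect_equal(vs_keys(filter_recessive(vs, "case", c("c1", "c2"))), vs_keys(vs)[2])
  expect_equal(n_variants(filter_recessive(vs, "case", c("c1", "c2"),
                                           missing_vetoes = TRUE)), 0L)
})

test_that("recessive filter matches the brute-force scan on random matrices", {
  set.seed(99)
  samples <- sprintf("S%02d", 1:20)
  for (rep in 1:10) {
    vs <- rand_variant_set(50, samples, missing_rate = 0.05)
    got <- vs_keys(filter_recessive(vs, "S01", samples[-1]))
    expect_equal(got, brute_recessive_keys(vs, "S01", samples[-1]))
    # funnel monotonicity: output is an order-preserving subset of input
    expect_true(all(got %in% vs_keys(vs)))
    expect_false(is.unsorted(match(got, vs_keys(vs))))
  }
})

test_that("X-linked modes keep X variants according to case carriage", {
  vs <- toy_set(rbind(
    c(1, 0, 0), # autosomal het
    c(1, 0, 0), # X het
    c(2, 0, 0)  # X hom
  ), chroms = c("1", "X", "X"))
  dom <- filter_x_linked(vs, "case", "x_linked_dominant")
  rec <- filter_x_linked(vs, "case", "x_linked_recessive")
  expect_equal(vs_keys(dom), vs_keys(vs)[2:3])
  expect_equal(vs_keys(rec), vs_keys(vs)[3])
})

test_that("unplaced-contig exclusion keeps placed chromosomes only", {
  vs <- toy_set(rbind(c(2, 0, 0), c(2, 0, 0), c(2, 0, 0)),
                chroms = c("2", "chrUn_00123", "X"))
  out <- exclude_unplaced(vs, c(as.character(1:38), "X"))
  expect_equal(out$variants$chrom, c("2", "X"))
  expect_equal(n_variants(exclude_unplaced(vs[0], "1")), 0L)
  expect_error(exclude_unplaced(vs, character(0)), "non-empty")
})

test_that("known-variant screen reports case genotypes and flags homozygosity", {
  vs <- toy_set(rbind(c(0, 1, 0), c(2, 0, 0), c(1, 0, 0)))
  loci <- data.frame(
    chrom = "1", pos = c(10L, 20L, 999L), ref = "A", alt = "T",
    label = c("known1", "known2", "known3"), stringsAsFactors = FALSE
  )
  scr <- known_variant_screen(vs, loci, "case")
  expect_equal(scr$case_genotype, c("hom_ref", "hom_alt", "absent"))
  expect_equal(attr(scr, "flagged"), "known2")
  clear <- known_variant_screen(vs[1], loci[1, ], "case")
  expect_length(attr(clear, "flagged"), 0L)
})
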