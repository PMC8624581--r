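# VCF reading/writing, genotype recoding, manifests, pedigrees

vcf_header <- function(samples) {
  c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##INFO=<ID=CSQ_TERMS,Number=1,Type=String,Description="c">',
    '##INFO=<ID=SIFT,Number=1,Type=Float,Description="s">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
}

write_fixture_vcf <- function(body, samples = c("S1", "S2", "S3", "S4")) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(samples), body), f)
  f
}

fixture_manifest <- function(ids) {
  data.frame(
    id = ids, breed = "B", cohort = "c",
    phenotype = c("case", rep("control", length(ids) - 1)),
    age_years = NA_real_,
    role = c("proband", rep("cross_genome_control", length(ids) - 1)),
    stringsAsFactors = FALSE
  )
}

test_that("a bi-allelic fixture yields one record per row with all genotypes", {
  f <- write_fixture_vcf(c(
    "1\t100\t.\tA\tT\t.\t.\tGENE=G1;CSQ_TERMS=missense_variant;SIFT=0.03\tGT\t1/1\t0/1\t0/0\t0/0",
    "2\t200\t.\tG\tC\t.\t.\tGENE=G2;CSQ_TERMS=intron_variant\tGT\t0/0\t0/0\t0/1\t1/1",
    "X\t300\t.\tT\tA\t.\t.\t.\tGT\t0/1\t0/0\t0/0\t./."
  ))
  vs <- read_vcf(f, fixture_manifest(c("S1", "S2", "S3", "S4")))
  expect_equal(n_variants(vs), 3L)
  expect_equal(ncol(vs$geno), 4L)
  expect_equal(vs$variants$gene, c("G1", "G2", ""))
  expect_equal(vs$variants$sift, c(0.03, NA, NA))
  expect_equal(unname(vs$geno[1, ]), c(2L, 1L, 0L, 0L))
  # "./." is missing, distinct from hom-ref
  expect_true(is.na(vs$geno[3, "S4"]))
  expect_equal(gt_label(vs$geno[3, "S4"]), "missing")
})

test_that("multi-allelic rows split into per-ALT records with recoded genotypes", {
  # hand-enumerated recodings for ALT = "A,T":
  #   1/2 -> het for each ALT; 2/2 -> (hom_ref, hom_alt); 0/1 -> (het, hom_ref)
  #   0/2 -> (hom_ref, het);   ./. -> missing on both
  f <- write_fixture_vcf(
    "3\t500\t.\tG\tA,T\t.\t.\t.\tGT\t1/2\t2/2\t0/1\t0/2",
    samples = c("S1", "S2", "S3", "S4")
  )
  vs <- read_vcf(f)
  expect_equal(n_variants(vs), 2L)
  expect_equal(vs$variants$alt, c("A", "T"))
  expect_equal(unname(vs$geno[1, ]), c(1L, 0L, 1L, 0L)) # vs ALT "A"
  expect_equal(unname(vs$geno[2, ]), c(1L, 2L, 0L, 1L)) # vs ALT "T"
})

test_that("splitting preserves the carried alternate-allele count per sample", {
  gts <- c("0/0", "0/1", "0/2", "0/3", "1/1", "1/2", "1/3", "2/2", "2/3", "3/3", "./.")
  body <- paste(c("5", "900", ".", "A", "C,G,T", ".", ".", ".", "GT", gts),
                collapse = "\t")
  f <- write_fixture_vcf(body, samples = sprintf("S%02d", seq_along(gts)))
  vs <- read_vcf(f)
  expect_equal(n_variants(vs), 3L)
  for (j in seq_along(gts)) {
    alleles <- suppressWarnings(as.integer(strsplit(gts[j], "/")[[1]]))
    expected <- if (any(is.na(alleles))) NA_integer_ else sum(alleles > 0)
    expect_equal(sum(vs$geno[, j]), expected, info = gts[j])
  }
})

test_that("VCF round-trip reproduces the record collection field by field", {
  set.seed(42)
  vs <- rand_variant_set(25, sprintf("S%02d", 1:6), missing_rate = 0.1)
  vs$variants$sift[1:5] <- c(0.03, 0.26, 0.5, NA, 1)
  f <- tempfile(fileext = ".vcf")
  write_vcf(vs, f)
  back <- read_vcf(f)
  expect_equal(back$variants, vs$variants)
  expect_equal(back$geno, vs$geno)
})

test_that("sample columns absent from the manifest raise a mismatch error", {
  f <- write_fixture_vcf("1\t1\t.\tA\tT\t.\t.\t.\tGT\t0/1\t0/0\t0/0\t0/0")
  expect_error(read_vcf(f, fixture_manifest(c("S1", "S2", "S3"))),
               "manifest-mismatch")
})

test_that("malformed GT fields report the offending line number", {
  f <- write_fixture_vcf("1\t1\t.\tA\tT\t.\t.\t.\tGT\t0/x\t0/0\t0/0\t0/0")
  expect_error(read_vcf(f), "GT field at line 7")
})

test_that("manifest validation enforces ids, proband count and control phenotype", {
  m <- fixture_manifest(c("A", "B"))
  expect_silent(validate_manifest(m))
  expect_error(validate_manifest(rbind(m, m[1, ])), "unique")
  m2 <- m
  m2$role <- "cross_genome_control"
  expect_error(validate_manifest(m2), "exactly one proband")
  m3 <- m
  m3$role[2] <- "breed_control"
  m3$phenotype[2] <- "unknown"
  expect_error(validate_manifest(m3), "phenotype 'control'")
})

test_that("a trio pedigree has two founders and parses from file", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsire\tdam", "KID\tPA\tMA", "PA\t0\t0", "MA\t0\t0"), f)
  ped <- read_pedigree(f)
  expect_setequal(founders(ped), c("PA", "MA"))
})

test_that("a parent cycle is rejected with the cycle listed", {
  expect_error(pedigree(c("A", "B"), c("B", "A"), c("0", "0")), "pedigree-cycle")
})

test_that("ancestor enumeration matches the hand-drawn five-generation pedigree", {
  # chain: P <- (F, M); F <- (FF, FM); FF <- (FFF, FFM); FFF <- (F4, .); F4 <- (F5, .)
  ped <- pedigree(
    id   = c("P", "F", "M", "FF", "FFF", "F4"),
    sire = c("F", "FF", "0", "FFF", "F4", "F5"),
    dam  = c("M", "FM", "0", "FFM", "0", "0")
  )
  anc3 <- vcfunnel:::ancestors_within(ped, "P", 3)
  # depth <= 3: P itself, F, M, FF, FM, FFF, FFM -> 7 entries
  expect_setequal(names(anc3), c("P", "F", "M", "FF", "FM", "FFF", "FFM"))
  anc5 <- vcfunnel:::ancestors_within(ped, "P", 5)
  expect_setequal(names(anc5),
                  c("P", "F", "M", "FF", "FM", "FFF", "FFM", "F4", "F5"))
  expect_equal(unname(anc5[c("F4", "F5")]), c(4L, 5L))
})
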