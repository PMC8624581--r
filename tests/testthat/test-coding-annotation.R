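# CDS coordinate arithmetic and protein-change annotation

test_that("CDS positions map to codon index and offset", {
  expect_equal(cds_to_codon(1222), list(codon = 408L, offset = 1L))
  expect_equal(cds_to_codon(1), list(codon = 1L, offset = 1L))
  expect_equal(cds_to_codon(6), list(codon = 2L, offset = 3L))
  expect_error(cds_to_codon(0), "coordinate error")
  expect_error(cds_to_codon(10, cds_length = 9), "coordinate error")
  # monotone non-decreasing in cds_pos
  codons <- vapply(1:60, function(p) cds_to_codon(p)$codon, integer(1))
  expect_false(is.unsorted(codons))
})

test_that("the synthetic gene model translates to 715 residues with GCA at 408", {
  m <- synthetic_bbs2_model()
  expect_equal(nchar(m$cds_sequence), 2145L)
  aa <- translate_cds(m$cds_sequence)
  expect_equal(nchar(aa), 715L)
  expect_false(grepl("\\*", aa))
  expect_equal(substr(m$cds_sequence, 1222, 1224), "GCA")
})

test_that("the G-to-C substitution at CDS 1222 is alanine-to-proline", {
  m <- synthetic_bbs2_model()
  pc <- annotate_substitution(m, 1222, "G", "C")
  expect_equal(pc$codon, 408L)
  expect_equal(pc$ref_codon, "GCA")
  expect_equal(pc$alt_codon, "CCA")
  expect_equal(pc$ref_aa, "Ala")
  expect_equal(pc$alt_aa, "Pro")
  expect_equal(pc$hgvs_p, "p.Ala408Pro")
  expect_equal(annotate_substitution(m, 1222, "G", "C", parens = TRUE)$hgvs_p,
               "p.(Ala408Pro)")
})

test_that("reference discordance and no-op substitutions are rejected", {
  m <- synthetic_bbs2_model()
  expect_error(annotate_substitution(m, 1222, "A", "C"), "reference-discordance")
  expect_error(annotate_substitution(m, 1222, "G", "G"), "must differ")
})

test_that("every third-position change within the GCx alanine family is synonymous", {
  # 4-fold degenerate codon: enumerate the family against the genetic code
  m <- synthetic_bbs2_model()
  ref3 <- substr(m$cds_sequence, 1224, 1224) # "A", third base of codon 408
  for (b in setdiff(c("A", "C", "G", "T"), ref3)) {
    pc <- annotate_substitution(m, 1224, ref3, b)
    expect_equal(pc$consequence, "synonymous")
    expect_equal(pc$ref_aa, "Ala")
    expect_equal(pc$alt_aa, "Ala")
    expect_equal(pc$hgvs_p, "p.Ala408=")
  }
})

test_that("genomic/CDS mapping is a strand-aware bijection on exonic positions", {
  m <- synthetic_bbs2_model()
  expect_equal(genomic_to_cds(m, m$exons$start[1]), 1L)
  expect_equal(genomic_to_cds(m, 59693737), 1222L)
  expect_equal(cds_to_genomic(m, 1222), 59693737L)
  set.seed(77)
  for (p in sample(nchar(m$cds_sequence), 100)) {
    expect_equal(genomic_to_cds(m, cds_to_genomic(m, p)), p)
  }
  # intronic position errors
  expect_error(genomic_to_cds(m, m$exons$end[1] + 1L), "not-in-CDS")
})

test_that("minus-strand mapping matches a hand-computed two-exon toy gene", {
  # exons in transcription order on '-': genomic [201,215] then [102,110],
  # widths 15 + 9 = 24 nt CDS; reading 5'->3' runs down the genomic axis
  exons <- data.frame(start = c(201L, 102L), end = c(215L, 110L))
  cds <- paste(rep("ATGGCA", 4), collapse = "") # 24 nt, no stops
  m <- gene_model("TOY", "-", exons, cds, chrom = "9")
  expect_equal(genomic_to_cds(m, 215), 1L)   # 5'-most base
  expect_equal(genomic_to_cds(m, 214), 2L)
  expect_equal(genomic_to_cds(m, 201), 15L)  # end of exon 1
  expect_equal(genomic_to_cds(m, 110), 16L)  # start of exon 2 (genomic top)
  expect_equal(genomic_to_cds(m, 102), 24L)
  expect_equal(cds_to_genomic(m, 16), 110L)
})

test_that("gene-model invariants are enforced", {
  exons <- data.frame(start = 1L, end = 9L)
  expect_error(gene_model("G", "+", exons, "ATGATG"), "does not match")
  expect_error(gene_model("G", "+", data.frame(start = 1L, end = 10L),
                          paste(rep("A", 10), collapse = "")), "divisible by 3")
  expect_error(gene_model("G", "+", exons, "ATGTAAGCATTT"), "does not match|internal stop")
  expect_error(gene_model("G", "+", exons, "ATGTAAGCA"), "internal stop")
})
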