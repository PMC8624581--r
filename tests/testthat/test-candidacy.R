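# Identifier mapping, keyword prioritization, gene-panel extraction

test_that("identifier mapping partitions ids into mapped and unmapped", {
  smap <- data.frame(id = c("ENS1", "ENS2"), symbol = c("BBS2", "RHO"),
                     stringsAsFactors = FALSE)
  mm <- map_identifiers(c("ENS1", "ENS3", "ENS2"), smap)
  expect_equal(mm$mapped$symbol, c("BBS2", "RHO"))
  expect_equal(mm$unmapped, "ENS3")
})

test_that("of 114 gene names with 84 resolvable, exactly 84 map through", {
  ids <- sprintf("ID%03d", 1:114)
  smap <- data.frame(id = ids[1:84], symbol = sprintf("SYM%03d", 1:84),
                     stringsAsFactors = FALSE)
  mm <- map_identifiers(ids, smap)
  expect_equal(nrow(mm$mapped), 84L)
  expect_equal(length(mm$unmapped), 30L)
})

test_that("keyword flagging is case-insensitive with word boundaries by default", {
  gpmap <- data.frame(
    gene = c("BBS2", "MYH7", "IFT88"),
    phenotype_text = c(
      "Retinal degeneration with Bardet-Biedl features",
      "Hypertrophic cardiomyopathy",
      "Abnormal ciliary assembly"
    ),
    stringsAsFactors = FALSE
  )
  out <- keyword_prioritize(gpmap, c("retinal", "cilia"))
  expect_equal(out$flagged, c(TRUE, FALSE, FALSE)) # "cilia" != "ciliary" as a word
  expect_equal(out$keywords[1], "retinal")
  sub <- keyword_prioritize(gpmap, c("retinal", "cilia"), mode = "substring")
  expect_equal(sub$flagged, c(TRUE, FALSE, TRUE))
  # hyphenated keywords are escaped, not treated as regex syntax
  bb <- keyword_prioritize(gpmap, "Bardet-Biedl")
  expect_true(bb$flagged[1])
})

test_that("adding keywords never unflags a gene", {
  gpmap <- data.frame(
    gene = sprintf("G%d", 1:6),
    phenotype_text = c("rod dystrophy", "cone loss", "renal cysts",
                       "obesity", "night blindness", "deafness"),
    stringsAsFactors = FALSE
  )
  base <- keyword_prioritize(gpmap, c("rod", "cone"))
  more <- keyword_prioritize(gpmap, c("rod", "cone", "blindness", "renal"))
  expect_true(all(more$flagged[base$flagged]))
})

panel_fixture_set <- function() {
  # 40 records, 9 of them in panel genes (by canonical name or synonym):
  # 4 exonic, 3 intronic, 1 UTR, 1 intergenic; "BBS10X" must NOT match
  genes <- c(
    "BBS2", "TTC8", "CEP290", "BBS1",          # panel, exonic
    "BBS9", "ARL6", "MKKS",                    # panel, intronic
    "BBS10", "BBS12",                          # panel, UTR / intergenic
    "BBS10X", "XBBS2",                         # near-miss names
    sprintf("OTHER%02d", 1:29)
  )
  csq <- c(
    "missense_variant", "stop_gained", "missense_variant", "synonymous_variant",
    "intron_variant", "intron_variant", "splice_region_variant",
    "3_prime_UTR_variant", "intergenic_variant",
    rep("missense_variant", 31)
  )
  variant_set(
    data.frame(chrom = "1", pos = seq_along(genes) * 100L, ref = "A", alt = "T",
               gene = genes, consequence = csq, stringsAsFactors = FALSE),
    matrix(2L, nrow = length(genes), ncol = 1, dimnames = list(NULL, "case"))
  )
}

test_that("panel extraction matches whole words including synonyms", {
  vs <- panel_fixture_set()
  out <- extract_gene_variants(vs, default_bbs_panel())
  expect_equal(n_variants(out), 9L)
  expect_true("TTC8" %in% out$variants$gene)          # synonym of BBS8
  expect_false("BBS10X" %in% out$variants$gene)       # whole-word semantics
  counts <- attr(out, "region_counts")
  expect_equal(unname(counts[c("exonic", "intronic", "UTR", "intergenic")]),
               c(4L, 3L, 1L, 1L))
})

test_that("panel extraction equals a text-level whole-word grep oracle", {
  vs <- panel_fixture_set()
  lines <- paste(vs$variants$chrom, vs$variants$pos, vs$variants$ref,
                 vs$variants$alt, vs$variants$gene)
  hit <- grepl(panel_regex(default_bbs_panel()), lines, perl = TRUE)
  expect_equal(vs_keys(extract_gene_variants(vs, default_bbs_panel())),
               vs_keys(vs)[hit])
})

test_that("the shipped syndrome panel has 21 canonical genes and reads from TSV", {
  p <- default_bbs_panel()
  expect_length(p$genes, 21L)
  shipped <- read_gene_panel(
    system.file("extdata", "bbs_panel.tsv", package = "vcfunnel")
  )
  expect_equal(shipped$genes, p$genes)
  expect_equal(shipped$synonyms[["BBS8"]], "TTC8")
  # synonym sets must be disjoint
  expect_error(gene_panel(c("A", "B"), list("X", "X")), "disjoint")
})
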