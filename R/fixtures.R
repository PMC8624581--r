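#' Packaged population-screening fixture
#'
#' A deterministic per-individual screening dataset for the worked
#' example: 1386 genotyped canids -- 505 of the case breed across five
#' genotyping cohorts, 15 crossbreeds, 8 wolves and 858 dogs of 154 other
#' breeds -- with a pedigree connecting the proband, its two affected
#' littermates and four heterozygous relatives through shared ancestors
#' within three parent-links. Aggregating this dataset reproduces the
#' published per-cohort, per-phenotype and per-breed genotype-count
#' tables of the worked example, including the relative-excluded allele
#' frequency. Individual ids, and the joint assignment of cohort x
#' phenotype x genotype (only its margins are published), are synthetic.
#'
#' @return list with `calls` (data.frame `id`, `breed`, `cohort`,
#'   `phenotype`, `gt`, `group`), `pedigree` (a [pedigree()]), `proband`,
#'   and `case_breed`.
#' @export
fixture_population <- function() {
  rows <- list()
  counter <- new.env()
  counter$i <- 0L
  add <- function(n, breed, cohort, phenotype, gt, group = breed, ids = NULL) {
    if (n == 0) return(invisible())
    if (is.null(ids)) {
      ids <- sprintf("DOG%04d", counter$i + seq_len(n))
      counter$i <- counter$i + n
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      id = ids, breed = breed, cohort = cohort, phenotype = phenotype,
      gt = gt, group = group, stringsAsFactors = FALSE
    )
  }
  ss <- CASE_BREED

  # original-litter probands and the two later-identified homozygotes
  add(1, ss, "AHT", "unknown", "hom_alt", ids = "SS1") # WGS proband
  add(2, ss, "AHT", "case", "hom_alt", ids = c("SS2", "SS3"))
  add(2, ss, "AHT", "control", "hom_alt", ids = c("SS4", "SS5"))
  # AHT heterozygotes: four are pedigree relatives of the proband
  add(4, ss, "AHT", "control", "het", ids = sprintf("REL%d", 1:4))
  add(7, ss, "AHT", "control", "het")
  add(2, ss, "AHT", "case", "hom_ref")
  add(29, ss, "AHT", "control", "hom_ref")
  add(44, ss, "AHT", "unknown", "hom_ref")
  # Helsinki cohort
  add(6, ss, "Helsinki", "unknown", "het")
  add(1, ss, "Helsinki", "case", "hom_ref")
  add(387, ss, "Helsinki", "unknown", "hom_ref")
  # Norwegian cohort: all submitted as PRA cases
  add(2, ss, "Norway", "case", "hom_alt", ids = c("SS6", "SS7"))
  add(6, ss, "Norway", "case", "hom_ref")
  # Pennsylvania family
  add(1, ss, "Pennsylvania", "case", "hom_ref")
  add(8, ss, "Pennsylvania", "unknown", "hom_ref")
  # case-breed genomes already in the genome bank
  add(3, ss, "genome_bank", "unknown", "hom_ref")

  # non-case-breed screening panel
  add(15, "Crossbreed", "screening", "unknown", "hom_ref", group = "crossbreeds")
  add(8, "Wolf", "screening", "unknown", "hom_ref", group = "wolves")
  n_other <- 858L
  other_breed <- sprintf("OtherBreed%03d", (seq_len(n_other) - 1L) %% 154L + 1L)
  rows[[length(rows) + 1L]] <- data.frame(
    id = sprintf("DOG%04d", counter$i + seq_len(n_other)),
    breed = other_breed, cohort = "screening", phenotype = "unknown",
    gt = "hom_ref", group = "154 other breeds", stringsAsFactors = FALSE
  )

  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL

  # litter SS1-SS3 shares SIRE/DAM; REL1-4 share grand-sire GSIRE through
  # UNCLE, i.e. within three parent-links of the proband
  ped <- pedigree(
    id   = c("SS1", "SS2", "SS3", "SIRE", "REL1", "REL2", "REL3", "REL4", "UNCLE"),
    sire = c("SIRE", "SIRE", "SIRE", "GSIRE", "UNCLE", "UNCLE", "UNCLE", "UNCLE", "GSIRE"),
    dam  = c("DAM", "DAM", "DAM", "GDAM", "RDAM", "RDAM", "RDAM", "RDAM", "GDAM2")
  )
  list(calls = calls, pedigree = ped, proband = "SS1", case_breed = ss)
}

#' Packaged genotype-count tables for the worked example
#'
#' Aggregates [fixture_population()] through [screen_population()] and
#' returns the three published tables of the worked example: per-cohort
#' genotype counts in the case breed, the phenotype-stratified table, and
#' per-breed-group counts with allele frequencies (including the row with
#' the proband's third-generation relatives excluded).
#'
#' @return list of data.frames `cohorts`, `phenotypes`, `breeds`, plus the
#'   full `screen` object.
#' @export
fixture_tables <- function() {
  fp <- fixture_population()
  scr <- screen_population(fp$calls, fp$proband, fp$pedigree,
                           case_breed = fp$case_breed)
  list(
    cohorts = scr$cohort_table,
    phenotypes = scr$phenotype_table,
    breeds = scr$breed_table,
    screen = scr
  )
}

#' Write the fixture tables as TSV files
#'
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written.
#' @export
write_fixture_tables <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ft <- fixture_tables()
  paths <- c(
    cohorts = file.path(dir, "cohort_genotypes.tsv"),
    phenotypes = file.path(dir, "phenotype_genotypes.tsv"),
    breeds = file.path(dir, "breed_frequencies.tsv")
  )
  for (nm in names(paths)) {
    utils::write.table(ft[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
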