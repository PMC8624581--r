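#' Population screening of a candidate variant
#'
#' Bookkeeping for genotyping a candidate variant across cohorts, breeds
#' and phenotype classes: per-cohort genotype tables for the case breed, a
#' phenotype-stratified table, per-breed-group allele frequencies, an
#' allele frequency with the proband's close relatives removed (so the
#' estimate represents the general population rather than the
#' ascertainment cluster), and a breed-privacy flag.
#'
#' The relative exclusion drops the proband *and* every individual related
#' to it within `relative_depth` parent-links (see
#' [relatives_within_generations()]); individuals absent from the pedigree
#' are assumed unrelated.
#'
#' @param calls data.frame with one genotyped individual per row: columns
#'   `id`, `breed`, `cohort`, `phenotype` (`case`/`control`/`unknown`),
#'   `gt` (state label or GT string), and optionally `group` (breed-group
#'   label for the frequency table; defaults to `breed`).
#' @param proband id of the index case (must appear in `calls`).
#' @param pedigree optional [pedigree()] for relative exclusion.
#' @param case_breed breed of the proband (default: looked up from `calls`).
#' @param relative_depth parent-link depth for relative exclusion (default 3).
#' @return An object of class `population_screen`: a list with
#'   `cohort_table`, `phenotype_table`, `breed_table` (each a data.frame of
#'   genotype counts; `breed_table` carries an `allele_frequency` column
#'   rounded half-up to 3 decimals and an `allele_frequency_raw` column),
#'   `n_genotyped`, `breed_private`, and `excluded_relatives`.
#' @export
screen_population <- function(calls, proband, pedigree = NULL,
                              case_breed = NULL, relative_depth = 3L) {
  if (nrow(calls) == 0) stop("screening call set is empty")
  stopifnot(all(c("id", "breed", "cohort", "phenotype", "gt") %in% names(calls)))
  if (!proband %in% calls$id) stop("unknown-individual: proband not among screening calls")
  if (is.null(case_breed)) case_breed <- calls$breed[calls$id == proband][1]
  calls$code <- gt_code(calls$gt)
  if (is.null(calls$group)) calls$group <- calls$breed

  ss <- calls[calls$breed == case_breed, , drop = FALSE]
  cohort_table <- stratified_table(ss$cohort, ss$code)
  phenotype_table <- stratified_table(ss$phenotype, ss$code,
                                      levels = c("case", "control", "unknown"))

  excluded <- character(0)
  if (!is.null(pedigree) && proband %in% pedigree$id) {
    rel <- relatives_within_generations(pedigree, proband, relative_depth)
    excluded <- intersect(c(proband, rel), calls$id)
  }
  ss_excl <- ss[!(ss$id %in% excluded), , drop = FALSE]

  breed_row <- function(label, codes) {
    c_ <- count_genotypes(codes)
    af <- if (c_$total > 0) allele_frequency(c_) else NA_real_
    data.frame(
      group = label, n_hom_alt = c_$n_hom_alt, n_het = c_$n_het,
      n_hom_ref = c_$n_hom_ref, total = c_$total,
      allele_frequency = round_half_up(af, 3), allele_frequency_raw = af,
      stringsAsFactors = FALSE
    )
  }
  others <- calls[calls$breed != case_breed, , drop = FALSE]
  rows <- list(breed_row(case_breed, ss$code))
  if (length(excluded) > 0) {
    rows[[2]] <- breed_row(paste0(case_breed, " (relatives excluded)"), ss_excl$code)
  }
  for (g in unique(others$group)) {
    rows[[length(rows) + 1L]] <- breed_row(g, others$code[others$group == g])
  }
  breed_table <- do.call(rbind, rows)

  breed_private <- !any(others$code >= 1L, na.rm = TRUE)
  structure(
    list(
      cohort_table = cohort_table, phenotype_table = phenotype_table,
      breed_table = breed_table, n_genotyped = sum(!is.na(calls$code)),
      breed_private = breed_private, excluded_relatives = excluded,
      case_breed = case_breed
    ),
    class = "population_screen"
  )
}

#' @export
print.population_screen <- function(x, ...) {
  cat("Population screen --", x$case_breed, "candidate variant\n")
  cat(x$n_genotyped, "individuals genotyped; breed-private:",
      x$breed_private, "\n\n")
  cat("case-breed cohorts:\n")
  print(x$cohort_table, row.names = FALSE)
  cat("\nphenotype strata:\n")
  print(x$phenotype_table, row.names = FALSE)
  cat("\nbreed groups:\n")
  print(x$breed_table[, setdiff(names(x$breed_table), "allele_frequency_raw")],
        row.names = FALSE)
  if (length(x$excluded_relatives) > 0) {
    cat("\nexcluded as proband/close relatives:",
        paste(x$excluded_relatives, collapse = ", "), "\n")
  }
  invisible(x)
}
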