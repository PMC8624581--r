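#' Genotype counts
#'
#' Count triple (hom-alt, het, hom-ref) for one variant in one stratum,
#' with missing calls tallied separately and excluded from the total.
#'
#' @param n_hom_alt,n_het,n_hom_ref,n_missing non-negative integers
#' @return An object of class `genotype_counts` with a `total` field
#'   (sum of the three called classes).
#' @export
genotype_counts <- function(n_hom_alt = 0L, n_het = 0L, n_hom_ref = 0L,
                            n_missing = 0L) {
  x <- c(n_hom_alt, n_het, n_hom_ref, n_missing)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  structure(
    list(
      n_hom_alt = as.integer(n_hom_alt), n_het = as.integer(n_het),
      n_hom_ref = as.integer(n_hom_ref), n_missing = as.integer(n_missing),
      total = as.integer(n_hom_alt + n_het + n_hom_ref)
    ),
    class = "genotype_counts"
  )
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("genotypes: ", x$n_hom_alt, " hom-alt / ", x$n_het, " het / ",
      x$n_hom_ref, " hom-ref (", x$total, " called",
      if (x$n_missing > 0) paste0(", ", x$n_missing, " missing") else "",
      ")\n", sep = "")
  invisible(x)
}

#' Count genotype states
#'
#' @param gt vector of genotype codes (0/1/2/NA) or state labels
#' @return A [genotype_counts()].
#' @export
count_genotypes <- function(gt) {
  if (is.character(gt)) gt <- gt_code(gt)
  genotype_counts(
    n_hom_alt = sum(gt == 2L, na.rm = TRUE),
    n_het = sum(gt == 1L, na.rm = TRUE),
    n_hom_ref = sum(gt == 0L, na.rm = TRUE),
    n_missing = sum(is.na(gt))
  )
}

#' Combine genotype counts across strata
#' @param ... `genotype_counts` objects (or a single list of them)
#' @return the summed [genotype_counts()].
#' @export
sum_genotype_counts <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && !inherits(cs[[1]], "genotype_counts")) cs <- cs[[1]]
  genotype_counts(
    sum(vapply(cs, `[[`, integer(1), "n_hom_alt")),
    sum(vapply(cs, `[[`, integer(1), "n_het")),
    sum(vapply(cs, `[[`, integer(1), "n_hom_ref")),
    sum(vapply(cs, `[[`, integer(1), "n_missing"))
  )
}

#' Alternate allele frequency from genotype counts
#'
#' `(2 * n_hom_alt + n_het) / (2 * total)` over called genotypes; missing
#' calls are excluded from the denominator, never imputed. The internal
#' value is unrounded; display rounding is half-up (see [round_half_up()]).
#'
#' @param counts a [genotype_counts()] (or anything with the three fields)
#' @return allele frequency in \[0,1\].
#' @export
allele_frequency <- function(counts) {
  total <- counts$n_hom_alt + counts$n_het + counts$n_hom_ref
  if (total == 0) stop("undefined-frequency: no called genotypes")
  (2 * counts$n_hom_alt + counts$n_het) / (2 * total)
}

#' Round half away from zero
#'
#' Decimal display rounding where a trailing 5 always rounds up
#' (0.0305 -> 0.031), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places (default 3, the table display convention)
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Genotype table by stratum
#'
#' One row of genotype counts per stratum (cohort, phenotype class,
#' breed, ...). Row totals sum to the number of called samples, so
#' stratified tables collapse to the unstratified count.
#'
#' @param strata character vector assigning each sample to exactly one
#'   stratum
#' @param gt parallel vector of genotype codes or state labels
#' @param levels optional stratum ordering (default: order of appearance)
#' @return data.frame `stratum`, `n_hom_alt`, `n_het`, `n_hom_ref`,
#'   `n_missing`, `total`.
#' @export
stratified_table <- function(strata, gt, levels = unique(strata)) {
  stopifnot(length(strata) == length(gt))
  if (is.character(gt)) gt <- gt_code(gt)
  rows <- lapply(levels, function(s) {
    c_ <- count_genotypes(gt[strata == s])
    data.frame(
      stratum = s, n_hom_alt = c_$n_hom_alt, n_het = c_$n_het,
      n_hom_ref = c_$n_hom_ref, n_missing = c_$n_missing, total = c_$total,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Relatives of a proband within g generations
#'
#' Returns every individual that shares at least one ancestor with the
#' proband, where the shared ancestor sits at most `g` parent-links above
#' *each* of the two individuals; direct ancestors and descendants within
#' `g` links are included (the individual or proband itself acting as the
#' shared "ancestor"). The proband is excluded from the returned set.
#' With `g = 3` this covers siblings, half-siblings and cousins up to
#' great-grandparental lines -- the operational definition of
#' "third-generation relatives" used for unbiased allele-frequency
#' estimates.
#'
#' @param ped a [pedigree()]
#' @param proband individual id (must be in the pedigree)
#' @param g generation depth (parent-links), `>= 1`
#' @return character vector of related individual ids.
#' @export
relatives_within_generations <- function(ped, proband, g = 3L) {
  stopifnot(g >= 1)
  anc_p <- ancestors_within(ped, proband, g) # includes proband at depth 0
  others <- setdiff(ped$id, proband)
  related <- vapply(others, function(id) {
    anc_i <- ancestors_within(ped, id, g)
    length(intersect(names(anc_p), names(anc_i))) > 0
  }, logical(1))
  unname(others[related])
}
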