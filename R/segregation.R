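#' Autosomal-recessive segregation filter
#'
#' Keeps a variant iff the case (proband) is homozygous for the alternate
#' allele and no control is. Heterozygous controls are permitted -- they
#' are the expected carriers of a recessive allele. A missing control call
#' is not evidence of homozygosity and by default does not veto retention;
#' set `missing_vetoes = TRUE` for the conservative alternative. A missing
#' case call always fails the case condition.
#'
#' @param vs a [variant_set()]
#' @param case_id sample id of the affected proband
#' @param control_ids sample ids of the (non-breed-matched) controls
#' @param missing_vetoes should a missing control genotype veto retention?
#' @return the surviving `variant_set`, input order preserved.
#' @export
filter_recessive <- function(vs, case_id, control_ids, missing_vetoes = FALSE) {
  case <- sample_geno(vs, case_id)
  keep <- !is.na(case) & case == 2L
  for (ctrl in control_ids) {
    g <- sample_geno(vs, ctrl)
    veto <- if (missing_vetoes) (is.na(g) | g == 2L) else (!is.na(g) & g == 2L)
    keep <- keep & !veto
  }
  vs[keep]
}

#' X-linked segregation filter
#'
#' Keeps variants on the X chromosome for which the case carries the
#' alternate allele: at least one copy under a dominant model, two copies
#' under a recessive model. Male hemizygous calls are whatever the caller
#' emitted on the diploid encoding; any GT carrying the ALT counts as a
#' carrier.
#'
#' @param vs a [variant_set()]
#' @param case_id sample id of the affected proband
#' @param mode `"x_linked_dominant"` or `"x_linked_recessive"`
#' @param x_chrom_name chromosome name of the X (default `"X"`)
#' @return the surviving `variant_set`, input order preserved.
#' @export
filter_x_linked <- function(vs, case_id,
                            mode = c("x_linked_dominant", "x_linked_recessive"),
                            x_chrom_name = "X") {
  mode <- match.arg(mode)
  stopifnot(nzchar(x_chrom_name))
  case <- sample_geno(vs, case_id)
  on_x <- vs$variants$chrom == x_chrom_name
  carries <- if (mode == "x_linked_dominant") {
    !is.na(case) & case >= 1L
  } else {
    !is.na(case) & case == 2L
  }
  vs[on_x & carries]
}

#' Exclude variants on unplaced contigs
#'
#' @param vs a [variant_set()]
#' @param placed_chroms non-empty character vector of placed chromosome
#'   names; everything else (e.g. `chrUn_*` contigs) is dropped.
#' @return the surviving `variant_set`, input order preserved.
#' @export
exclude_unplaced <- function(vs, placed_chroms) {
  if (length(placed_chroms) == 0) stop("placed_chroms must be non-empty")
  vs[vs$variants$chrom %in% placed_chroms]
}

#' Screen the case against previously published variants
#'
#' Before hunting for a novel variant, the case genome is checked at each
#' previously published disease locus. The screen reports the case
#' genotype at every known locus and raises a flag if the case is
#' homozygous for any published alternate allele -- in which case the
#' disease is likely not novel.
#'
#' @param vs a [variant_set()] (the full callset)
#' @param known_loci data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   and optionally `label`
#' @param case_id sample id of the proband
#' @return data.frame of `chrom`, `pos`, `ref`, `alt`, `label`,
#'   `case_genotype` (state label or `"absent"`), with attribute
#'   `flagged`: the labels of loci where the case is hom-alt (empty when
#'   the run may proceed).
#' @export
known_variant_screen <- function(vs, known_loci, case_id) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(known_loci)))
  if (is.null(known_loci$label)) {
    known_loci$label <- paste0(known_loci$chrom, ":", known_loci$pos)
  }
  keys <- variant_key(known_loci)
  idx <- match(keys, vs$variants$key)
  case <- sample_geno(vs, case_id)
  geno <- ifelse(is.na(idx), "absent", gt_label(case[idx]))
  out <- data.frame(
    chrom = known_loci$chrom, pos = as.integer(known_loci$pos),
    ref = known_loci$ref, alt = known_loci$alt, label = known_loci$label,
    case_genotype = geno, stringsAsFactors = FALSE
  )
  attr(out, "flagged") <- out$label[out$case_genotype == "hom_alt"]
  out
}
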