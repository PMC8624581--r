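#' Genome banks
#'
#' A genome bank is a panel of control genomes from many breeds used to
#' discard common polymorphisms. It is stored sparsely: only carrier calls
#' are recorded, and an absent (genome, variant) pair means
#' hom-ref-or-uncalled, i.e. non-carrier.
#'
#' @param genomes data.frame with columns `genome_id`, `breed` (ids unique)
#' @param calls data.frame with columns `genome_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gt` (genotype state label or GT string)
#' @return An object of class `genome_bank`.
#' @export
genome_bank <- function(genomes, calls) {
  stopifnot(all(c("genome_id", "breed") %in% names(genomes)))
  if (anyDuplicated(genomes$genome_id)) stop("bank genome ids must be unique")
  stopifnot(all(c("genome_id", "chrom", "pos", "ref", "alt", "gt") %in% names(calls)))
  bad <- setdiff(calls$genome_id, genomes$genome_id)
  if (length(bad) > 0) stop("bank calls reference unknown genome(s): ", paste(bad, collapse = ", "))
  calls$key <- variant_key(calls)
  calls$code <- gt_code(calls$gt)
  calls$breed <- genomes$breed[match(calls$genome_id, genomes$genome_id)]
  structure(list(genomes = genomes, calls = calls), class = "genome_bank")
}

#' Read a genome bank from TSV
#'
#' TSV with header `genome_id breed chrom pos ref alt gt`; one row per
#' carrier call. Genomes never appearing in a row for a variant are
#' non-carriers of it. Genomes with no calls at all may be declared with
#' `gt` empty or `hom_ref` so their breed is known.
#'
#' @param path TSV file path
#' @return A [genome_bank()].
#' @export
read_genome_bank <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  genomes <- unique(t[, c("genome_id", "breed")])
  calls <- t[nzchar(t$chrom), , drop = FALSE]
  calls$pos <- as.integer(calls$pos)
  genome_bank(genomes, calls[, c("genome_id", "chrom", "pos", "ref", "alt", "gt")])
}

# Keys of variants carried (at >= min_code copies) by any non-exempt bank
# genome.
bank_hit_keys <- function(bank, exempt_breeds, min_code) {
  calls <- bank$calls
  hit <- !is.na(calls$code) & calls$code >= min_code &
    !(calls$breed %in% exempt_breeds)
  unique(calls$key[hit])
}

#' Genome-bank absence filter
#'
#' Keeps a variant iff no non-exempt bank genome carries the alternate
#' allele at all (neither het nor hom-alt). This is the strict
#' "absent from all other genomes" criterion; breeds closely related to
#' the case breed can be exempted because a breed-private recessive may
#' legitimately segregate there.
#'
#' @param vs a [variant_set()]
#' @param bank a [genome_bank()]
#' @param exempt_breeds character vector of breed names whose genomes do
#'   not count against a variant (may be empty)
#' @return the surviving `variant_set`, input order preserved.
#' @export
bank_absence_filter <- function(vs, bank, exempt_breeds = character(0)) {
  hits <- bank_hit_keys(bank, exempt_breeds, min_code = 1L)
  vs[!(vs$variants$key %in% hits)]
}

#' Genome-bank homozygosity filter
#'
#' Keeps a variant unless at least `min_hom_genomes` non-exempt bank
#' genomes are homozygous for the alternate allele. Heterozygous bank
#' carriers never disqualify under this filter (they may be carriers of a
#' rare recessive); any cross-breed homozygote does, because a fully
#' penetrant recessive cannot be homozygous in a healthy genome of an
#' unaffected breed.
#'
#' @inheritParams bank_absence_filter
#' @param min_hom_genomes number of non-exempt hom-alt genomes required to
#'   exclude (default 1, the strictest reading of "multiple")
#' @return the surviving `variant_set`, input order preserved.
#' @export
bank_homozygosity_filter <- function(vs, bank, exempt_breeds = character(0),
                                     min_hom_genomes = 1L) {
  calls <- bank$calls
  hom <- !is.na(calls$code) & calls$code == 2L & !(calls$breed %in% exempt_breeds)
  tab <- table(calls$key[hom])
  bad <- names(tab)[tab >= min_hom_genomes]
  vs[!(vs$variants$key %in% bad)]
}

#' SIFT tolerance filter
#'
#' Removes variants predicted tolerated by SIFT (score above the
#' deleterious threshold). Variants without a SIFT score are kept: absence
#' of a prediction is not evidence of tolerance.
#'
#' @param vs a [variant_set()]
#' @param threshold deleterious/tolerated boundary in \[0,1\] (default 0.05,
#'   SIFT's conventional cutoff; scores `<=` threshold are deleterious)
#' @return the surviving `variant_set`, input order preserved.
#' @export
sift_filter <- function(vs, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 1)
  s <- vs$variants$sift
  vs[is.na(s) | s <= threshold]
}
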