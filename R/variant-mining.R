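#' Post-funnel exclusion by genotyping breed-matched controls
#'
#' After the genome-wide funnel, each surviving candidate is genotyped in
#' aged, phenotype-clear, breed-matched controls. Under a fully penetrant
#' recessive model a candidate is excluded as causal as soon as one
#' eligible control is homozygous for its alternate allele; heterozygous
#' controls never exclude (carriers are expected). Candidates with no
#' control call at all (e.g. assay failure) are carried forward as
#' unresolved, ranked below retained ones.
#'
#' @param candidates a [variant_set()] of funnel survivors
#' @param control_calls data.frame with columns `sample_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gt` (state label or GT string)
#' @param manifest manifest data.frame (see [read_manifest()]); eligible
#'   controls have `role == "breed_control"`, `phenotype == "control"` and
#'   `age_years >= min_age`. Calls from ineligible samples are dropped
#'   with a warning.
#' @param min_age minimum control age in years (default 8)
#' @return data.frame of dispositions: `key`, `gene`, `status` (one of
#'   `excluded_control_homozygote`, `unresolved_assay_failure`,
#'   `retained`), `evidence` free text. Statuses partition the candidates.
#' @export
control_genotype_exclusion <- function(candidates, control_calls, manifest,
                                       min_age = 8) {
  stopifnot(all(c("sample_id", "chrom", "pos", "ref", "alt", "gt") %in% names(control_calls)))
  eligible <- manifest$id[
    manifest$role == "breed_control" &
      manifest$phenotype == "control" &
      !is.na(manifest$age_years) & manifest$age_years >= min_age
  ]
  known <- control_calls$sample_id %in% manifest$id
  if (any(!known)) {
    stop("control calls reference sample(s) not in manifest: ",
         paste(unique(control_calls$sample_id[!known]), collapse = ", "))
  }
  ok <- control_calls$sample_id %in% eligible
  if (any(!ok)) {
    warning(
      "ignoring calls from ", length(unique(control_calls$sample_id[!ok])),
      " control(s) failing eligibility (age/phenotype/role)"
    )
    control_calls <- control_calls[ok, , drop = FALSE]
  }
  control_calls$key <- variant_key(control_calls)
  control_calls$code <- gt_code(control_calls$gt)

  keys <- vs_keys(candidates)
  status <- character(length(keys))
  evidence <- character(length(keys))
  for (i in seq_along(keys)) {
    calls <- control_calls[control_calls$key == keys[i], , drop = FALSE]
    calls <- calls[!is.na(calls$code), , drop = FALSE]
    if (nrow(calls) == 0) {
      status[i] <- "unresolved_assay_failure"
      evidence[i] <- "no eligible control call obtained"
    } else if (any(calls$code == 2L)) {
      hom <- calls$sample_id[calls$code == 2L]
      status[i] <- "excluded_control_homozygote"
      evidence[i] <- paste0(
        "hom-alt in ", length(hom), " eligible control(s): ",
        paste(utils::head(hom, 5), collapse = ", ")
      )
    } else {
      status[i] <- "retained"
      evidence[i] <- paste0(
        sum(calls$code == 1L), " het / ", sum(calls$code == 0L),
        " hom-ref among ", nrow(calls), " eligible control calls"
      )
    }
  }
  data.frame(
    key = keys, gene = candidates$variants$gene, status = status,
    evidence = evidence, stringsAsFactors = FALSE
  )
}
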