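#' Effect-score tables
#'
#' An effect-score table maps each consequence term of the controlled
#' vocabulary to an integer severity score in 0--5, and designates a set of
#' "high effect" scores (default `{4, 5}`). The default table places
#' truncating and canonical splice-site classes at 5; missense, in-frame
#' indels and splice-region at 4; synonymous-like classes at 3; UTR and
#' up/downstream at 2; intron and intergenic at 1; and unannotated at 0.
#' The table is user-overridable (see [read_effect_scores()]).
#'
#' @param scores named integer vector: consequence term -> score in 0..5.
#' @param high_scores integer vector of scores counting as "high effect".
#' @return An object of class `effect_score_table`.
#' @export
effect_score_table <- function(scores = default_effect_scores(), high_scores = c(4L, 5L)) {
  scores <- vapply(scores, as.integer, integer(1))
  if (any(scores < 0L | scores > 5L)) stop("effect scores must lie in [0, 5]")
  high_scores <- as.integer(high_scores)
  if (any(!high_scores %in% 0:5)) stop("high_scores must be a subset of 0..5")
  structure(list(scores = scores, high_scores = sort(high_scores)),
            class = "effect_score_table")
}

#' Default consequence-term score map
#'
#' @return named integer vector over the controlled consequence vocabulary.
#' @export
default_effect_scores <- function() {
  c(
    stop_gained = 5L, stop_lost = 5L, start_lost = 5L,
    frameshift_variant = 5L, splice_acceptor_variant = 5L,
    splice_donor_variant = 5L,
    missense_variant = 4L, inframe_insertion = 4L, inframe_deletion = 4L,
    splice_region_variant = 4L,
    synonymous_variant = 3L, stop_retained_variant = 3L,
    start_retained_variant = 3L,
    `5_prime_UTR_variant` = 2L, `3_prime_UTR_variant` = 2L,
    upstream_gene_variant = 2L, downstream_gene_variant = 2L,
    intron_variant = 1L, intergenic_variant = 1L
  )
}

#' Read an effect-score table override from TSV
#'
#' Two-column TSV `term score`; scores must be integers in 0--5.
#'
#' @param path TSV file path
#' @inheritParams effect_score_table
#' @return An `effect_score_table`.
#' @export
read_effect_scores <- function(path, high_scores = c(4L, 5L)) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term", "score") %in% names(t))) {
    stop("effect-score TSV must have columns: term, score")
  }
  effect_score_table(stats::setNames(as.integer(t$score), t$term), high_scores)
}

#' Score a single consequence-term set
#'
#' Returns the maximum mapped score over the terms (worst-consequence
#' convention). An empty term set is the unannotated class and scores 0.
#'
#' @param consequences character vector of consequence terms, or a single
#'   `&`-joined string as stored in a [variant_set()].
#' @param table an [effect_score_table()]
#' @return integer score in 0..5
#' @export
score_variant <- function(consequences, table = effect_score_table()) {
  terms <- unlist(strsplit(consequences, "&", fixed = TRUE))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) return(0L)
  unknown <- setdiff(terms, names(table$scores))
  if (length(unknown) > 0) {
    stop("unknown-consequence: term(s) not in score table: ",
         paste(unknown, collapse = ", "))
  }
  max(table$scores[terms])
}

#' Score every variant in a set
#'
#' @param vs a [variant_set()]
#' @inheritParams score_variant
#' @return integer vector of scores, one per record.
#' @export
score_variants <- function(vs, table = effect_score_table()) {
  vapply(vs$variants$consequence, score_variant, integer(1), table = table,
         USE.NAMES = FALSE)
}

#' Is a score in the high-effect set?
#'
#' @param score integer score(s) in 0..5
#' @inheritParams score_variant
#' @return logical vector
#' @export
is_high_effect <- function(score, table = effect_score_table()) {
  if (any(!score %in% 0:5)) stop("scores must lie in [0, 5]")
  score %in% table$high_scores
}

#' Keep only high-effect variants
#'
#' @param vs a [variant_set()]
#' @inheritParams score_variant
#' @return the surviving `variant_set`, input order preserved.
#' @export
filter_high_effect <- function(vs, table = effect_score_table()) {
  vs[is_high_effect(score_variants(vs, table), table)]
}
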