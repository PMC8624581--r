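#' Variant sets
#'
#' A `variant_set` bundles a per-variant table with a per-sample genotype
#' matrix. It is the container every funnel filter consumes and returns,
#' so filters compose and per-stage survivor counts can be audited.
#'
#' The variant table has one row per bi-allelic site with columns
#' `chrom`, `pos` (1-based), `ref`, `alt`, `gene` (symbol or stable
#' identifier, may be `""`), `consequence` (`&`-joined consequence terms,
#' may be `""` for unannotated sites) and `sift` (numeric in \[0,1\] or `NA`).
#' Genotypes are coded as the count of alternate alleles carried:
#' 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing. A missing call is
#' deliberately distinct from hom-ref and never satisfies a filter
#' predicate.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `gene`, `consequence`, `sift`.
#' @param genotypes integer matrix, one row per variant, one named column per
#'   sample; entries in `{0, 1, 2, NA}`.
#' @return An object of class `variant_set`.
#' @examples
#' v <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "T")
#' g <- matrix(c(2L, 1L), nrow = 1, dimnames = list(NULL, c("case", "ctrl")))
#' variant_set(v, g)
#' @export
variant_set <- function(variants, genotypes) {
  stopifnot(is.data.frame(variants), is.matrix(genotypes))
  if (nrow(variants) != nrow(genotypes)) {
    stop("variant table and genotype matrix must have the same number of rows")
  }
  if (nrow(genotypes) > 0 && ncol(genotypes) > 0 && is.null(colnames(genotypes))) {
    stop("genotype matrix must have sample names as column names")
  }
  for (col in c("gene", "consequence")) {
    if (is.null(variants[[col]])) variants[[col]] <- ""
    variants[[col]][is.na(variants[[col]])] <- ""
  }
  if (is.null(variants$sift)) variants$sift <- NA_real_
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  storage.mode(genotypes) <- "integer"
  if (any(!genotypes %in% c(0L, 1L, 2L, NA))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  variants <- variants[, c("chrom", "pos", "ref", "alt", "gene", "consequence", "sift")]
  variants$key <- variant_key(variants)
  rownames(variants) <- NULL
  structure(list(variants = variants, geno = genotypes), class = "variant_set")
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Number of variants in a set
#' @param vs a `variant_set`
#' @return integer count of records
#' @export
n_variants <- function(vs) nrow(vs$variants)

#' Sample identifiers carried by a variant set
#' @param vs a `variant_set`
#' @return character vector of sample ids (genotype matrix columns)
#' @export
vs_samples <- function(vs) colnames(vs$geno)

#' Variant keys (`chrom:pos:ref:alt`)
#' @param vs a `variant_set`
#' @return character vector of keys, in record order
#' @export
vs_keys <- function(vs) vs$variants$key

#' @export
`[.variant_set` <- function(x, i, ...) {
  structure(
    list(
      variants = x$variants[i, , drop = FALSE],
      geno = x$geno[i, , drop = FALSE]
    ),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat(
    "<variant_set> ", n_variants(x), " variants x ",
    ncol(x$geno), " samples\n",
    sep = ""
  )
  if (n_variants(x) > 0) {
    print(utils::head(x$variants[, c("chrom", "pos", "ref", "alt", "gene", "consequence")], 6))
    if (n_variants(x) > 6) cat("...\n")
  }
  invisible(x)
}

# Genotype of one sample at each record, as the 0/1/2/NA code.
sample_geno <- function(vs, sample_id) {
  if (!sample_id %in% colnames(vs$geno)) {
    stop("manifest-mismatch: sample '", sample_id, "' not present in the callset")
  }
  vs$geno[, sample_id]
}

GT_LABELS <- c("hom_ref", "het", "hom_alt")

#' Translate genotype codes to state labels
#'
#' @param code integer vector of 0/1/2/NA genotype codes
#' @return character vector over `hom_ref`, `het`, `hom_alt`, `missing`
#' @export
gt_label <- function(code) {
  out <- ifelse(is.na(code), "missing", GT_LABELS[code + 1L])
  unname(out)
}

#' Translate genotype state labels (or GT strings) to codes
#'
#' Accepts the state labels `hom_ref`/`het`/`hom_alt`/`missing` as well as
#' diploid VCF GT strings such as `0/1` or `1|1` (any `.` allele makes the
#' call missing).
#'
#' @param x character vector of labels or GT strings
#' @return integer vector of 0/1/2/NA codes
#' @export
gt_code <- function(x) {
  out <- rep(NA_integer_, length(x))
  lab <- match(x, GT_LABELS)
  out[!is.na(lab)] <- lab[!is.na(lab)] - 1L
  gtish <- is.na(lab) & x != "missing" & !is.na(x)
  if (any(gtish)) {
    parts <- strsplit(x[gtish], "[/|]")
    out[gtish] <- vapply(parts, function(a) {
      if (any(a == ".")) return(NA_integer_)
      n <- suppressWarnings(as.integer(a))
      if (any(is.na(n))) stop("malformed genotype string: ", paste(a, collapse = "/"))
      sum(n > 0L)
    }, integer(1))
  }
  out
}
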