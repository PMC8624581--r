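#' Read a multi-sample VCF into a variant set
#'
#' Parses a VCF v4.2 file (fixed columns plus per-sample GT) into a
#' [variant_set()]. Each multi-allelic row is split into one record per
#' alternate allele, and every sample's genotype is recoded against that
#' allele as the number of copies carried: a `1/2` call therefore becomes
#' `het` on both split records, and never `hom_alt` on either. Records
#' preserve file order (split records stay adjacent, in ALT order).
#'
#' Gene symbol, consequence terms and SIFT score are taken from INFO keys;
#' annotation dialects differ, so the key names are arguments. Consequence
#' terms are `&`-separated within the key (the VCF INFO comma is reserved
#' for per-ALT lists). Only the GT FORMAT subfield is interpreted.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param manifest optional [read_manifest()] data.frame; when supplied,
#'   every sample column of the VCF must appear in it.
#' @param gene_key,csq_key,sift_key INFO key names carrying the gene symbol,
#'   consequence terms and SIFT score (defaults `GENE`, `CSQ_TERMS`, `SIFT`).
#' @return A [variant_set()] with one record per bi-allelic ALT.
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path, manifest = NULL,
                     gene_key = "GENE", csq_key = "CSQ_TERMS", sift_key = "SIFT") {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) stop("VCF parse error in '", path, "': ", conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_row <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(manifest)) {
    missing_ids <- setdiff(samples, manifest$id)
    if (length(missing_ids) > 0) {
      stop(
        "manifest-mismatch: VCF sample(s) not in manifest: ",
        paste(missing_ids, collapse = ", ")
      )
    }
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = n_row, dimnames = list(NULL, samples))
  }
  # line number of each data row, for error messages
  n_meta <- length(vcf@meta)

  info_field <- function(key) {
    if (n_row == 0) return(character(0))
    out <- vcfR::extract.info(vcf, element = key)
    if (is.null(out)) rep(NA_character_, n_row) else out
  }
  genes <- info_field(gene_key)
  csqs <- info_field(csq_key)
  sifts <- suppressWarnings(as.numeric(info_field(sift_key)))

  rows <- vector("list", n_row)
  for (r in seq_len(n_row)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    line_no <- n_meta + 1L + r
    # parse allele lists once per sample
    alleles <- strsplit(gt_raw[r, ], "[/|]")
    counts <- lapply(alleles, function(a) {
      if (length(a) == 0 || any(is.na(a))) return(NA_integer_)
      if (any(a == ".")) return(rep(NA_integer_, length(alts)))
      n <- suppressWarnings(as.integer(a))
      if (any(is.na(n)) || any(n > length(alts))) {
        stop("VCF parse error: malformed GT field at line ", line_no)
      }
      vapply(seq_along(alts), function(i) sum(n == i), integer(1))
    })
    counts <- lapply(counts, function(x) {
      if (length(x) == 1 && is.na(x[1])) rep(NA_integer_, length(alts)) else x
    })
    cnt <- do.call(rbind, counts) # samples x alts
    sub <- data.frame(
      chrom = unname(fix[r, "CHROM"]),
      pos = as.integer(fix[r, "POS"]),
      ref = unname(fix[r, "REF"]),
      alt = alts,
      gene = if (is.na(genes[r])) "" else genes[r],
      consequence = if (is.na(csqs[r])) "" else csqs[r],
      sift = sifts[r],
      stringsAsFactors = FALSE
    )
    g <- t(cnt)
    colnames(g) <- samples
    rows[[r]] <- list(v = sub, g = g)
  }
  variants <- do.call(rbind, lapply(rows, `[[`, "v"))
  geno <- do.call(rbind, lapply(rows, `[[`, "g"))
  if (is.null(variants)) {
    variants <- data.frame(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), gene = character(0), consequence = character(0),
      sift = numeric(0)
    )
    geno <- matrix(integer(0), nrow = 0, ncol = length(samples),
                   dimnames = list(NULL, samples))
  }
  variant_set(variants, geno)
}

#' Write a variant set as a VCF v4.2 file
#'
#' Serializes a [variant_set()] to plain-text VCF: one bi-allelic row per
#' record, genotypes as unphased diploid GT, and the gene / consequence /
#' SIFT annotations in the INFO keys named by the arguments. Reading the
#' file back with [read_vcf()] reproduces the set field-by-field.
#'
#' @param vs a `variant_set`
#' @param path output file path
#' @inheritParams read_vcf
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path,
                      gene_key = "GENE", csq_key = "CSQ_TERMS", sift_key = "SIFT") {
  v <- vs$variants
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Gene symbol or identifier">', gene_key),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Ampersand-joined consequence terms">', csq_key),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="SIFT score">', sift_key),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vs$geno)), collapse = "\t")
  )
  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- character(0)
    if (nzchar(v$gene[i])) parts <- c(parts, paste0(gene_key, "=", v$gene[i]))
    if (nzchar(v$consequence[i])) parts <- c(parts, paste0(csq_key, "=", v$consequence[i]))
    if (!is.na(v$sift[i])) {
      parts <- c(parts, paste0(sift_key, "=", format(v$sift[i], trim = TRUE, scientific = FALSE)))
    }
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, character(1))
  gt_strings <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(i) {
    g <- vs$geno[i, ]
    gs <- ifelse(is.na(g), "./.", gt_strings[g + 1L])
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", ".",
            info[i], "GT", gs), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest is a TSV with header
#' `id breed cohort phenotype age_years role`. Phenotypes are one of
#' `case`, `control`, `unknown`; roles are one of `proband`,
#' `breed_control`, `cross_genome_control`, `bank`. The reader enforces
#' unique ids, exactly one proband, and that breed-matched controls are
#' phenotypically clear (`phenotype == "control"`).
#'
#' @param path TSV file path
#' @return data.frame with the six manifest columns.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_manifest(m)
}

#' Validate (and normalize) a sample manifest
#' @param m data.frame with columns `id`, `breed`, `cohort`, `phenotype`,
#'   `age_years`, `role`
#' @return the validated data.frame, `age_years` coerced to numeric.
#' @export
validate_manifest <- function(m) {
  needed <- c("id", "breed", "cohort", "phenotype", "age_years", "role")
  if (!all(needed %in% names(m))) {
    stop("manifest must have columns: ", paste(needed, collapse = ", "))
  }
  m$age_years <- suppressWarnings(as.numeric(m$age_years))
  if (anyDuplicated(m$id)) stop("manifest ids must be unique")
  bad_ph <- setdiff(unique(m$phenotype), c("case", "control", "unknown"))
  if (length(bad_ph) > 0) stop("unknown phenotype value(s): ", paste(bad_ph, collapse = ", "))
  bad_role <- setdiff(unique(m$role), c("proband", "breed_control", "cross_genome_control", "bank"))
  if (length(bad_role) > 0) stop("unknown role value(s): ", paste(bad_role, collapse = ", "))
  if (sum(m$role == "proband") != 1) {
    stop("manifest must contain exactly one proband (found ", sum(m$role == "proband"), ")")
  }
  bc <- m$role == "breed_control"
  if (any(m$phenotype[bc] != "control")) {
    stop("breed_control samples must have phenotype 'control'")
  }
  m
}

#' Read a pedigree
#'
#' PED-like TSV with columns `id`, `sire`, `dam`; `"0"` (or empty) marks a
#' founder on that side. Parent ids that never appear as an `id` row are
#' treated as implicit founders. The pedigree is validated to be acyclic.
#'
#' @param path TSV file path
#' @return An object of class `pedigree`: a data.frame of `id`, `sire`,
#'   `dam` with `NA` for founder slots.
#' @export
read_pedigree <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "sire", "dam") %in% names(p))) {
    stop("pedigree must have columns: id, sire, dam")
  }
  pedigree(p$id, p$sire, p$dam)
}

#' Construct a pedigree from parallel vectors
#'
#' @param id individual ids (unique)
#' @param sire,dam parent ids; `"0"`, `""` or `NA` mark founders
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(id, sire, dam) {
  norm <- function(x) {
    x[is.na(x) | x == "0" | x == ""] <- NA_character_
    x
  }
  p <- data.frame(
    id = as.character(id), sire = norm(as.character(sire)),
    dam = norm(as.character(dam)), stringsAsFactors = FALSE
  )
  if (anyDuplicated(p$id)) stop("pedigree ids must be unique")
  # implicit founders: parents with no row of their own
  implicit <- setdiff(stats::na.omit(c(p$sire, p$dam)), p$id)
  if (length(implicit) > 0) {
    p <- rbind(p, data.frame(id = implicit, sire = NA_character_, dam = NA_character_))
  }
  cyc <- find_pedigree_cycle(p)
  if (!is.null(cyc)) {
    stop("pedigree-cycle: ", paste(cyc, collapse = " -> "))
  }
  structure(p, class = c("pedigree", "data.frame"))
}

# Depth-first search for a cycle through parent links; returns the cycle
# path or NULL.
find_pedigree_cycle <- function(p) {
  parents <- function(i) stats::na.omit(c(p$sire[i], p$dam[i]))
  idx <- stats::setNames(seq_len(nrow(p)), p$id)
  state <- integer(nrow(p)) # 0 unseen, 1 in-stack, 2 done
  cycle <- NULL
  visit <- function(i, path) {
    if (state[i] == 1L) {
      cycle <<- c(path[which(path == p$id[i])[1]:length(path)], p$id[i])
      return(TRUE)
    }
    if (state[i] == 2L) return(FALSE)
    state[i] <<- 1L
    for (pa in parents(i)) {
      if (visit(idx[[pa]], c(path, p$id[i]))) return(TRUE)
    }
    state[i] <<- 2L
    FALSE
  }
  for (i in seq_len(nrow(p))) {
    if (state[i] == 0L && visit(i, character(0))) break
  }
  cycle
}

#' Founders of a pedigree
#' @param ped a [pedigree()]
#' @return character vector of ids with neither parent recorded
#' @export
founders <- function(ped) {
  ped$id[is.na(ped$sire) & is.na(ped$dam)]
}

# All ancestors of `id` within `g` parent-links, as a named integer vector
# of minimal link depth (id itself included at depth 0).
ancestors_within <- function(ped, id, g) {
  if (!id %in% ped$id) stop("unknown-individual: '", id, "' not in pedigree")
  depth <- stats::setNames(0L, id)
  frontier <- id
  d <- 0L
  while (length(frontier) > 0 && d < g) {
    d <- d + 1L
    rows <- ped[ped$id %in% frontier, , drop = FALSE]
    nxt <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), names(depth))
    if (length(nxt) > 0) depth[nxt] <- d
    frontier <- nxt
  }
  depth
}
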