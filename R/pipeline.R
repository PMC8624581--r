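#' Run the full variant-prioritization funnel
#'
#' Executes, in order: the known-variant screen (if loci are supplied), the
#' high-effect filter, autosomal-recessive segregation (with an X-linked
#' side branch reported for completeness), unplaced-contig exclusion, then
#' two parallel branches -- (A) genome-bank absence and (B) gene candidacy
#' (SIFT tolerance, bank homozygosity, identifier mapping, phenotype
#' keywords) -- whose survivors are intersected into the final candidate
#' set, which is then genotyped in aged breed-matched controls and, where a
#' gene model is available, annotated at the protein level. The two
#' branches are also reported side by side, since either can be audited on
#' its own.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `vcf`, `manifest`, `bank`, `control_calls`, `gene_phenotypes` (file
#'   paths); optional `known_loci`, `symbol_map`, `effect_scores`,
#'   `keywords` (file path or character vector), `placed_chroms` (default
#'   autosomes 1--38 plus X), `x_chrom` (default `"X"`), `exempt_breeds`
#'   (default: the proband's breed), `sift_threshold` (default 0.05),
#'   `min_hom_genomes` (default 1), `min_control_age` (default 8),
#'   `high_scores` (default 4,5), `keyword_mode` (default `"word"`).
#' @param gene_models optional named list of [gene_model()] objects (by
#'   gene symbol) used to annotate retained candidates.
#' @param quiet suppress per-stage log lines on standard error?
#' @return An object of class `funnel_report`; see [report_json()].
#' @export
run_pipeline <- function(config, gene_models = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("vcf", "manifest", "bank", "control_calls", "gene_phenotypes")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0) stop("config must name inputs: ", paste(miss, collapse = ", "))
  get <- function(nm, default) if (is.null(config[[nm]])) default else config[[nm]]

  log_stage <- function(branch, stage, n_in, n_out) {
    if (!quiet) {
      message(sprintf("[%s] %-18s in=%d out=%d excluded=%d",
                      branch, stage, n_in, n_out, n_in - n_out))
    }
  }
  stages <- list()
  add_stage <- function(branch, stage, n_in, n_out) {
    stages[[length(stages) + 1L]] <<- data.frame(
      branch = branch, stage = stage, n_in = n_in, n_out = n_out,
      stringsAsFactors = FALSE
    )
    log_stage(branch, stage, n_in, n_out)
  }

  manifest <- read_manifest(config$manifest)
  vs <- read_vcf(config$vcf, manifest)
  case_id <- manifest$id[manifest$role == "proband"]
  control_ids <- intersect(
    manifest$id[manifest$role == "cross_genome_control"], vs_samples(vs)
  )
  case_breed <- manifest$breed[manifest$role == "proband"]

  table <- if (is.null(config$effect_scores)) {
    effect_score_table(high_scores = get("high_scores", c(4L, 5L)))
  } else {
    read_effect_scores(config$effect_scores, high_scores = get("high_scores", c(4L, 5L)))
  }
  bank <- read_genome_bank(config$bank)
  gpmap <- read_gene_phenotypes(config$gene_phenotypes)
  keywords <- get("keywords", default_pra_keywords())
  if (is.character(keywords) && length(keywords) == 1 && file.exists(keywords)) {
    keywords <- read_keywords(keywords)
  }
  symbol_map <- if (is.null(config$symbol_map)) NULL else {
    utils::read.delim(config$symbol_map, stringsAsFactors = FALSE)
  }
  placed <- get("placed_chroms", c(as.character(1:38), "X"))
  x_chrom <- get("x_chrom", "X")
  exempt <- get("exempt_breeds", case_breed)
  sift_thr <- get("sift_threshold", 0.05)
  min_hom <- get("min_hom_genomes", 1L)
  min_age <- get("min_control_age", 8)

  known <- NULL
  if (!is.null(config$known_loci)) {
    loci <- utils::read.delim(config$known_loci, stringsAsFactors = FALSE,
                              colClasses = "character")
    loci$pos <- as.integer(loci$pos)
    known <- known_variant_screen(vs, loci, case_id)
    if (length(attr(known, "flagged")) > 0 && !quiet) {
      message("known-variant screen FLAG: case hom-alt at ",
              paste(attr(known, "flagged"), collapse = ", "))
    }
  }

  # serial trunk
  v_high <- filter_high_effect(vs, table)
  add_stage("trunk", "high_effect", n_variants(vs), n_variants(v_high))
  v_ar <- filter_recessive(v_high, case_id, control_ids)
  add_stage("trunk", "recessive", n_variants(v_high), n_variants(v_ar))
  v_pl <- exclude_unplaced(v_ar, placed)
  add_stage("trunk", "unplaced", n_variants(v_ar), n_variants(v_pl))

  # X-linked side branch (reported, not merged into the trunk)
  x_dom <- filter_x_linked(v_high, case_id, "x_linked_dominant", x_chrom)
  x_rec <- filter_x_linked(v_high, case_id, "x_linked_recessive", x_chrom)
  add_stage("x_linked", "x_dominant", n_variants(v_high), n_variants(x_dom))
  add_stage("x_linked", "x_recessive", n_variants(v_high), n_variants(x_rec))

  # branch A: genome-bank absence
  a_bank <- bank_absence_filter(v_pl, bank, exempt)
  add_stage("bank_absence", "bank_absence", n_variants(v_pl), n_variants(a_bank))

  # branch B: candidacy
  b_sift <- sift_filter(v_pl, sift_thr)
  add_stage("candidacy", "sift", n_variants(v_pl), n_variants(b_sift))
  b_hom <- bank_homozygosity_filter(b_sift, bank, exempt, min_hom)
  add_stage("candidacy", "bank_homozygosity", n_variants(b_sift), n_variants(b_hom))
  genes_in <- unique(b_hom$variants$gene)
  mm <- if (is.null(symbol_map)) {
    list(mapped = data.frame(id = genes_in, symbol = genes_in,
                             stringsAsFactors = FALSE),
         unmapped = character(0))
  } else {
    map_identifiers(genes_in, symbol_map)
  }
  b_map <- b_hom[b_hom$variants$gene %in% mm$mapped$id]
  add_stage("candidacy", "identifier_mapping", n_variants(b_hom), n_variants(b_map))
  sym <- mm$mapped$symbol[match(b_map$variants$gene, mm$mapped$id)]
  kw <- keyword_prioritize(gpmap, keywords, genes = unique(sym),
                           mode = get("keyword_mode", "word"))
  flagged <- kw$gene[kw$flagged]
  b_kw <- b_map[sym %in% flagged]
  add_stage("candidacy", "keyword", n_variants(b_map), n_variants(b_kw))

  final_keys <- intersect(vs_keys(a_bank), vs_keys(b_kw))
  candidates <- v_pl[vs_keys(v_pl) %in% final_keys]
  add_stage("final", "branch_intersection",
            length(union(vs_keys(a_bank), vs_keys(b_kw))), n_variants(candidates))

  control_calls <- utils::read.delim(config$control_calls,
                                     stringsAsFactors = FALSE,
                                     colClasses = "character")
  control_calls$pos <- as.integer(control_calls$pos)
  dispositions <- control_genotype_exclusion(candidates, control_calls,
                                             manifest, min_age)
  add_stage("final", "control_genotyping", n_variants(candidates),
            sum(dispositions$status == "retained"))

  # retained first, unresolved carried below them
  keep <- dispositions$status %in% c("retained", "unresolved_assay_failure")
  ranked <- dispositions[keep, , drop = FALSE]
  ranked <- ranked[order(ranked$status != "retained"), , drop = FALSE]

  annot <- lapply(seq_len(nrow(ranked)), function(i) {
    key <- ranked$key[i]
    v <- candidates$variants[candidates$variants$key == key, ][1, ]
    gm <- gene_models[[v$gene]]
    if (is.null(gm) || nchar(v$ref) != 1 || nchar(v$alt) != 1) return(NULL)
    cds_pos <- tryCatch(genomic_to_cds(gm, v$pos), error = function(e) NULL)
    if (is.null(cds_pos)) return(NULL)
    pc <- annotate_substitution(gm, cds_pos, v$ref, v$alt)
    data.frame(key = key, gene = v$gene, cds_pos = cds_pos,
               hgvs_c = paste0("c.", cds_pos, v$ref, ">", v$alt),
               hgvs_p = pc$hgvs_p, consequence = pc$consequence,
               stringsAsFactors = FALSE)
  })
  annot <- do.call(rbind, annot[!vapply(annot, is.null, logical(1))])

  accounting <- funnel_accounting(
    vs, trunk = list(high_effect = v_high, recessive = v_ar, unplaced = v_pl),
    branch_a = list(bank_absence = a_bank),
    branch_b = list(sift = b_sift, bank_homozygosity = b_hom,
                    identifier_mapping = b_map, keyword = b_kw),
    dispositions = dispositions
  )

  structure(
    list(
      stages = do.call(rbind, stages),
      known_screen = known,
      branches = list(bank_absence = vs_keys(a_bank), candidacy = vs_keys(b_kw)),
      x_linked = list(dominant = vs_keys(x_dom), recessive = vs_keys(x_rec)),
      dispositions = dispositions,
      retained = ranked,
      annotation = annot,
      accounting = accounting,
      unmapped_genes = mm$unmapped,
      case_id = case_id, case_breed = case_breed
    ),
    class = "funnel_report"
  )
}

# One row per input variant with its first-cause disposition: the trunk
# stage that removed it, else the branch stage(s), else its control-
# genotyping status.
funnel_accounting <- function(vs, trunk, branch_a, branch_b, dispositions) {
  keys <- vs_keys(vs)
  stage_lost <- function(pipe, keys) {
    out <- rep("passed", length(keys))
    alive <- rep(TRUE, length(keys))
    for (nm in names(pipe)) {
      surv <- keys %in% vs_keys(pipe[[nm]])
      out[alive & !surv] <- nm
      alive <- alive & surv
    }
    out
  }
  trunk_stage <- stage_lost(trunk, keys)
  in_trunk_out <- trunk_stage == "passed"
  a_stage <- rep(NA_character_, length(keys))
  b_stage <- rep(NA_character_, length(keys))
  a_stage[in_trunk_out] <- stage_lost(branch_a, keys[in_trunk_out])
  b_stage[in_trunk_out] <- stage_lost(branch_b, keys[in_trunk_out])
  final <- rep(NA_character_, length(keys))
  m <- match(keys, dispositions$key)
  final[!is.na(m)] <- dispositions$status[m[!is.na(m)]]
  first_cause <- ifelse(
    trunk_stage != "passed", trunk_stage,
    ifelse(a_stage != "passed", a_stage,
           ifelse(b_stage != "passed", b_stage, final))
  )
  data.frame(
    key = keys, trunk = trunk_stage, bank_branch = a_stage,
    candidacy_branch = b_stage, final = final, first_cause = first_cause,
    stringsAsFactors = FALSE
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Variant-prioritization funnel\n")
  cat("case:", x$case_id, "(", x$case_breed, ")\n\n")
  print(x$stages, row.names = FALSE)
  if (!is.null(x$known_screen)) {
    fl <- attr(x$known_screen, "flagged")
    cat("\nknown-variant screen:",
        if (length(fl) == 0) "clear" else paste("FLAG at", paste(fl, collapse = ", ")),
        "\n")
  }
  cat("\nfinal candidates:\n")
  if (nrow(x$retained) == 0) {
    cat("  (none retained)\n")
  } else {
    print(x$retained[, c("key", "gene", "status")], row.names = FALSE)
  }
  if (!is.null(x$annotation) && nrow(x$annotation) > 0) {
    cat("\nprotein-level annotation:\n")
    print(x$annotation, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a funnel report to JSON
#'
#' Deterministic (no timestamps): re-running the pipeline on identical
#' inputs yields byte-identical JSON.
#'
#' @param report a `funnel_report`
#' @param path optional output file; when `NULL` the JSON string is
#'   returned
#' @return the JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(
    schema = "vcfunnel-report/1",
    case = list(id = report$case_id, breed = report$case_breed),
    stages = report$stages,
    branches = report$branches,
    x_linked = report$x_linked,
    dispositions = report$dispositions,
    retained = report$retained,
    annotation = report$annotation,
    unmapped_genes = report$unmapped_genes
  )
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, na = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
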