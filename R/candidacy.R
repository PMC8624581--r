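#' Map gene identifiers to symbols
#'
#' Partitions a vector of gene identifiers (e.g. Ensembl stable ids with
#' no attached symbol) into those resolvable through a supplied
#' id-to-symbol table and those not. Orthology lookup is data, not
#' computation: unmapped ids are excluded downstream with a logged reason.
#'
#' @param genes character vector of gene ids/symbols
#' @param symbol_map data.frame with columns `id`, `symbol` (or a named
#'   character vector id -> symbol)
#' @return list with `mapped` (data.frame `id`, `symbol`) and `unmapped`
#'   (character vector).
#' @export
map_identifiers <- function(genes, symbol_map) {
  if (is.data.frame(symbol_map)) {
    stopifnot(all(c("id", "symbol") %in% names(symbol_map)))
    symbol_map <- stats::setNames(symbol_map$symbol, symbol_map$id)
  }
  hit <- genes %in% names(symbol_map)
  list(
    mapped = data.frame(
      id = genes[hit], symbol = unname(symbol_map[genes[hit]]),
      stringsAsFactors = FALSE
    ),
    unmapped = genes[!hit]
  )
}

#' Read a gene-to-phenotype text map
#'
#' TSV with columns `gene`, `phenotype_text`; one locally supplied,
#' OMIM-style free-text phenotype description per gene. Symbols must be
#' unique after case folding.
#'
#' @param path TSV file path
#' @return data.frame `gene`, `phenotype_text`.
#' @export
read_gene_phenotypes <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("gene", "phenotype_text") %in% names(t)))
  if (anyDuplicated(tolower(t$gene))) stop("gene symbols must be unique (case-insensitive)")
  t
}

#' Default retinal-degeneration keyword list
#'
#' An editable, PRA-oriented default; the operation, not the list, is the
#' contribution. One keyword per line when supplied as a file
#' ([read_keywords()]).
#'
#' @return character vector of keywords.
#' @export
default_pra_keywords <- function() {
  c(
    "retina", "retinal", "retinitis", "photoreceptor", "rod", "cone",
    "blindness", "ciliopathy", "Bardet-Biedl", "macular", "degeneration"
  )
}

#' Read a keyword list (one keyword per line)
#' @param path plain-text file path
#' @return character vector of keywords (deduplicated case-insensitively).
#' @export
read_keywords <- function(path) {
  k <- readLines(path)
  k <- trimws(k)
  k <- k[nzchar(k)]
  if (length(k) == 0) stop("keyword list must be non-empty")
  k[!duplicated(tolower(k))]
}

#' Flag candidate genes by phenotype-keyword cross-reference
#'
#' A gene is flagged iff at least one keyword occurs (case-insensitively)
#' in its phenotype description. The default `"word"` mode requires a
#' whole-word occurrence (so `cilia` does not match `ciliary`);
#' `"substring"` mode relaxes this.
#'
#' @param gpmap data.frame `gene`, `phenotype_text` (see
#'   [read_gene_phenotypes()])
#' @param keywords character vector of phenotype keywords
#' @param genes optional character vector restricting which genes to assess
#' @param mode `"word"` (word-boundary match) or `"substring"`
#' @return data.frame `gene`, `flagged` (logical), `keywords`
#'   (comma-joined matched keywords, `""` when unflagged).
#' @export
keyword_prioritize <- function(gpmap, keywords = default_pra_keywords(),
                               genes = NULL, mode = c("word", "substring")) {
  mode <- match.arg(mode)
  if (length(keywords) == 0) stop("keyword list must be non-empty")
  if (!is.null(genes)) gpmap <- gpmap[gpmap$gene %in% genes, , drop = FALSE]
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", keywords)
  pats <- if (mode == "word") paste0("\\b", esc, "\\b") else esc
  matched <- lapply(gpmap$phenotype_text, function(txt) {
    keywords[vapply(pats, grepl, logical(1), x = txt, ignore.case = TRUE, perl = TRUE)]
  })
  data.frame(
    gene = gpmap$gene,
    flagged = lengths(matched) > 0,
    keywords = vapply(matched, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Gene panels
#'
#' A panel of canonical gene names with synonym sets, used to pull every
#' variant in a fixed gene list out of a callset regardless of effect
#' score (e.g. all genes implicated in a syndrome).
#'
#' @param genes character vector of canonical gene names
#' @param synonyms list (parallel to `genes`) of character vectors of
#'   synonyms; synonym sets must be disjoint across canonical names
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(genes, synonyms = vector("list", length(genes))) {
  stopifnot(length(genes) == length(synonyms))
  synonyms <- lapply(synonyms, function(s) if (is.null(s)) character(0) else s)
  all_tokens <- c(genes, unlist(synonyms))
  if (anyDuplicated(all_tokens)) {
    stop("panel names/synonyms must be disjoint: ",
         paste(unique(all_tokens[duplicated(all_tokens)]), collapse = ", "))
  }
  structure(list(genes = genes, synonyms = stats::setNames(synonyms, genes)),
            class = "gene_panel")
}

#' Read a gene panel from TSV
#'
#' TSV with columns `gene`, `synonyms` (comma-joined, may be empty).
#'
#' @param path TSV file path
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("gene", "synonyms") %in% names(t)))
  syn <- lapply(strsplit(t$synonyms, ",", fixed = TRUE), function(s) s[nzchar(trimws(s))])
  gene_panel(t$gene, syn)
}

#' The 21-gene Bardet-Biedl syndrome panel
#'
#' Canonical names with synonyms (`BBS8`/`TTC8`, `BBIP1`/`BBIP10`) for the
#' 21 genes implicated in human Bardet-Biedl syndrome, as used for
#' panel-wide variant extraction from a whole-genome callset.
#'
#' @return A [gene_panel()] of 21 canonical genes.
#' @export
default_bbs_panel <- function() {
  genes <- c(
    "BBS1", "BBS2", "ARL6", "BBS4", "BBS5", "MKKS", "BBS7", "BBS8",
    "BBS9", "BBS10", "TRIM32", "BBS12", "MKS1", "CEP290", "WDPCP",
    "SDCCA8", "LZTFL1", "BBIP1", "IFT27", "IFT172", "C8orf37"
  )
  syn <- stats::setNames(vector("list", length(genes)), genes)
  syn[["BBS8"]] <- "TTC8"
  syn[["BBIP1"]] <- "BBIP10"
  gene_panel(genes, unname(syn[genes]))
}

panel_tokens <- function(panel) {
  unique(c(panel$genes, unlist(panel$synonyms)))
}

#' Whole-word regular expression for a gene panel
#'
#' The alternation pattern whose whole-word application to serialized
#' variant lines reproduces a `grep -wE` panel extraction.
#'
#' @param panel a [gene_panel()]
#' @return a single regex string `\\b(tok1|tok2|...)\\b`.
#' @export
panel_regex <- function(panel) {
  paste0("\\b(", paste(panel_tokens(panel), collapse = "|"), ")\\b")
}

# Coarse region class of a consequence-term string.
classify_region <- function(consequence) {
  terms <- strsplit(consequence, "&", fixed = TRUE)
  vapply(terms, function(tt) {
    if (any(tt %in% c(
      "missense_variant", "synonymous_variant", "stop_gained", "stop_lost",
      "start_lost", "frameshift_variant", "inframe_insertion",
      "inframe_deletion", "stop_retained_variant", "start_retained_variant"
    ))) return("exonic")
    if (any(tt %in% c("5_prime_UTR_variant", "3_prime_UTR_variant"))) return("UTR")
    if (any(tt %in% c("intron_variant", "splice_acceptor_variant",
                      "splice_donor_variant", "splice_region_variant"))) {
      return("intronic")
    }
    if (any(tt %in% c("intergenic_variant", "upstream_gene_variant",
                      "downstream_gene_variant"))) return("intergenic")
    "other"
  }, character(1))
}

#' Extract all variants in a gene panel
#'
#' Pulls every record (any effect score) whose gene attribution matches a
#' panel gene or synonym as a whole word, case-sensitively -- mirroring a
#' `grep -wE "(BBS1|BBS2|...)"` extraction over serialized variant lines.
#' Surviving records are categorized by coarse region class
#' (exonic / intronic / UTR / intergenic / other) from their consequence
#' terms.
#'
#' @param vs a [variant_set()] with gene attributions
#' @param panel a [gene_panel()]
#' @return the matching `variant_set`, with a `region` column added to its
#'   variant table and a `region_counts` attribute (named integer vector).
#' @export
extract_gene_variants <- function(vs, panel) {
  hit <- grepl(panel_regex(panel), vs$variants$gene, perl = TRUE)
  out <- vs[hit]
  out$variants$region <- classify_region(out$variants$consequence)
  attr(out, "region_counts") <- c(table(out$variants$region))
  out
}
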