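#' Gene models for coding annotation
#'
#' A minimal gene model: ordered exons (1-based closed genomic intervals,
#' listed in transcription order 5'->3') plus the spliced CDS on the
#' coding strand. The CDS length must be divisible by 3, match the summed
#' exon widths, and translate without an internal stop.
#'
#' @param gene gene symbol
#' @param strand `"+"` or `"-"`
#' @param exons data.frame with columns `start`, `end` (genomic, closed);
#'   rows in transcription order (descending genomic coordinates on `-`)
#' @param cds_sequence spliced coding-strand nucleotide string
#' @param chrom chromosome name (default `""`)
#' @param metadata optional list of pass-through annotation (e.g. externally
#'   predicted protein-domain boundaries); not computed here
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, strand, exons, cds_sequence, chrom = "",
                       metadata = list()) {
  stopifnot(strand %in% c("+", "-"), all(c("start", "end") %in% names(exons)))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end < exons$start)) stop("exon end before start")
  o <- order(exons$start)
  so <- exons[o, ]
  if (any(so$start[-1] <= so$end[-nrow(so)])) stop("exons must not overlap")
  genomic_order <- if (strand == "+") !is.unsorted(exons$start) else !is.unsorted(rev(exons$start))
  if (!genomic_order) stop("exons must be listed in transcription order (5'->3')")
  cds_sequence <- toupper(cds_sequence)
  widths <- exons$end - exons$start + 1L
  if (sum(widths) != nchar(cds_sequence)) {
    stop("CDS length (", nchar(cds_sequence), ") does not match summed exon widths (",
         sum(widths), ")")
  }
  if (nchar(cds_sequence) %% 3 != 0) stop("CDS length must be divisible by 3")
  aa <- translate_cds(cds_sequence)
  if (grepl("\\*", substr(aa, 1, nchar(aa) - 1))) {
    stop("CDS translation contains an internal stop codon")
  }
  structure(
    list(gene = gene, strand = strand, chrom = chrom, exons = exons,
         cds_sequence = cds_sequence, metadata = metadata),
    class = "gene_model"
  )
}

#' Translate a CDS with the standard genetic code
#' @param cds nucleotide string (length divisible by 3)
#' @return single-letter amino-acid string.
#' @export
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

# 1-letter -> 3-letter amino-acid code, stop as "Ter".
aa3 <- function(aa1) {
  code <- c(Biostrings::AMINO_ACID_CODE, "*" = "Ter")
  out <- code[aa1]
  if (any(is.na(out))) stop("unknown amino acid: ", paste(aa1[is.na(out)], collapse = ", "))
  unname(out)
}

#' Map a CDS position to its codon
#'
#' @param cds_pos 1-based position on the coding sequence
#' @param cds_length optional CDS length for range validation
#' @return list with `codon` (index, `ceiling(cds_pos/3)`) and `offset`
#'   (position within the codon, 1..3).
#' @export
cds_to_codon <- function(cds_pos, cds_length = NULL) {
  cds_pos <- as.integer(cds_pos)
  if (cds_pos < 1L) stop("coordinate error: CDS position must be >= 1")
  if (!is.null(cds_length) && cds_pos > cds_length) {
    stop("coordinate error: CDS position ", cds_pos, " beyond CDS length ", cds_length)
  }
  list(codon = as.integer(ceiling(cds_pos / 3)),
       offset = as.integer((cds_pos - 1L) %% 3L + 1L))
}

#' Annotate a coding substitution at protein level
#'
#' Checks the supplied reference base against the model's CDS, applies the
#' substitution, translates the affected codon and emits the HGVS-style
#' protein change. Missense changes give `p.Ala408Pro`-style strings;
#' synonymous changes give `p.Ala408=`. Parenthesized output
#' (`p.(Ala408Pro)`) is available via `parens`.
#'
#' @param model a [gene_model()]
#' @param cds_pos 1-based CDS position of the substituted base
#' @param ref_base,alt_base single reference / alternate bases (must differ)
#' @param parens wrap the change in parentheses (predicted-consequence
#'   HGVS style)?
#' @return list with `codon` (index), `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa` (3-letter codes), `consequence` (`"missense"`/`"synonymous"`/
#'   `"nonsense"`), and `hgvs_p`.
#' @export
annotate_substitution <- function(model, cds_pos, ref_base, alt_base,
                                  parens = FALSE) {
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  stopifnot(nchar(ref_base) == 1, nchar(alt_base) == 1)
  if (ref_base == alt_base) stop("ref and alt bases must differ")
  n <- nchar(model$cds_sequence)
  loc <- cds_to_codon(cds_pos, cds_length = n)
  have <- substr(model$cds_sequence, cds_pos, cds_pos)
  if (have != ref_base) {
    stop("reference-discordance: CDS position ", cds_pos, " is '", have,
         "', not '", ref_base, "'")
  }
  c0 <- (loc$codon - 1L) * 3L + 1L
  ref_codon <- substr(model$cds_sequence, c0, c0 + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, loc$offset, loc$offset) <- alt_base
  ref_aa1 <- translate_cds(ref_codon)
  alt_aa1 <- translate_cds(alt_codon)
  ref_aa <- aa3(ref_aa1)
  alt_aa <- aa3(alt_aa1)
  consequence <- if (ref_aa1 == alt_aa1) "synonymous"
    else if (alt_aa1 == "*") "nonsense" else "missense"
  change <- if (consequence == "synonymous") paste0(ref_aa, loc$codon, "=")
    else paste0(ref_aa, loc$codon, alt_aa)
  hgvs_p <- if (parens) paste0("p.(", change, ")") else paste0("p.", change)
  list(codon = loc$codon, ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence,
       hgvs_p = hgvs_p)
}

#' Genomic to CDS coordinate
#'
#' Strand-aware cumulative exon offset: the inverse of [cds_to_genomic()]
#' on every exonic position.
#'
#' @param model a [gene_model()]
#' @param chrom_pos 1-based genomic position
#' @return 1-based CDS position.
#' @export
genomic_to_cds <- function(model, chrom_pos) {
  chrom_pos <- as.integer(chrom_pos)
  cum <- 0L
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons$start[i]
    e <- model$exons$end[i]
    if (chrom_pos >= s && chrom_pos <= e) {
      off <- if (model$strand == "+") chrom_pos - s + 1L else e - chrom_pos + 1L
      return(cum + off)
    }
    cum <- cum + (e - s + 1L)
  }
  stop("not-in-CDS: position ", chrom_pos, " falls in no exon of ", model$gene)
}

#' CDS to genomic coordinate
#'
#' @param model a [gene_model()]
#' @param cds_pos 1-based CDS position
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(model, cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (cds_pos < 1L || cds_pos > nchar(model$cds_sequence)) {
    stop("coordinate error: CDS position out of range")
  }
  cum <- 0L
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons$start[i]
    e <- model$exons$end[i]
    w <- e - s + 1L
    if (cds_pos <= cum + w) {
      off <- cds_pos - cum
      return(if (model$strand == "+") s + off - 1L else e - off + 1L)
    }
    cum <- cum + w
  }
  stop("unreachable")
}

#' Synthetic stand-in gene model for the worked example
#'
#' A deterministic, fully synthetic 715-codon gene model (2145 nt CDS, 15
#' exons on the plus strand of chromosome "2") built so that the worked
#' missense example is reproducible offline: codon 408 is `GCA` (alanine),
#' CDS position 1222 is its first base and maps to genomic position
#' 59,693,737, inside exon 11. The sequence is generated from a fixed
#' codon rotation and is *not* the real canine BBS2 CDS; only its length,
#' the codon at position 408 and the coordinate layout are arranged to
#' match the worked example. Externally predicted protein-domain
#' boundaries are carried as pass-through metadata.
#'
#' @return A [gene_model()] named `BBS2`.
#' @export
synthetic_bbs2_model <- function() {
  n_codon <- 715L
  pool <- c("GCT", "TGG", "CAT", "GAA", "CTG", "AAA", "GAC", "TTC",
            "ATC", "CCG", "AGT", "TAC", "GTG", "AAC", "CGA", "ACC")
  codons <- pool[(seq_len(n_codon) - 1L) %% length(pool) + 1L]
  codons[1] <- "ATG"
  codons[408] <- "GCA"
  cds <- paste(codons, collapse = "")
  widths <- c(rep(120L, 10L), 100L, 211L, 211L, 211L, 212L)
  stopifnot(sum(widths) == 3L * n_codon)
  intron <- 500L
  # anchor: CDS position 1222 (offset 22 of exon 11) at chr2:59,693,737
  gene_start <- 59693737L - 21L - (sum(widths[1:10]) + 10L * intron)
  starts <- integer(length(widths))
  s <- gene_start
  for (i in seq_along(widths)) {
    starts[i] <- s
    s <- s + widths[i] + intron
  }
  exons <- data.frame(start = starts, end = starts + widths - 1L)
  gene_model(
    gene = "BBS2", strand = "+", exons = exons, cds_sequence = cds,
    chrom = "2",
    metadata = list(
      protein_length = n_codon,
      domains = data.frame(
        name = c("N-terminal", "mid", "C-terminal", "coiled-coil"),
        start = c(22L, 159L, 270L, 317L), end = c(120L, 266L, 709L, 344L)
      )
    )
  )
}
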