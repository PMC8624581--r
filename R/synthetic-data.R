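#' Simulation configuration for synthetic cohorts
#'
#' Defines the study design the generator emulates: one affected proband
#' sequenced against a panel of non-breed-matched control genomes, a
#' larger multi-breed genome bank, and a set of aged breed-matched
#' controls genotyped after the funnel. Defaults mirror that design at
#' desk scale: 1 case, 176 cross-breed control genomes in the callset,
#' a 648-genome bank (including 3 genomes of the case breed), 43 aged
#' breed-matched controls, and 500 variants -- one planted causal
#' homozygous missense variant plus labelled decoys, each violating
#' exactly one funnel criterion.
#'
#' @param seed integer seed; the same seed yields byte-identical output files.
#' @param n_case number of cases (must be 1; the funnel is single-proband).
#' @param n_breed_controls aged breed-matched controls genotyped post-funnel.
#' @param n_cross_controls non-breed-matched control genomes in the callset.
#' @param n_bank_genomes genome-bank size.
#' @param n_breeds number of non-case breeds.
#' @param n_variants total variants (planted + decoys).
#' @param n_genes number of simulated genes besides the planted gene.
#' @param planted list describing the causal variant: `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `consequence`, `cds_pos`, `sift`.
#' @param carrier_freq_in_breed het frequency of the causal allele among
#'   breed-matched controls (never hom-alt there).
#' @param het_rate_controls background het rate of decoy alleles in
#'   cross-breed controls.
#' @param decoys named integer vector of decoy counts per class
#'   (`low_effect`, `case_not_hom`, `control_hom`, `unplaced`,
#'   `bank_carrier`, `sift_tolerated`, `no_keyword`); `NULL` for default
#'   proportions of `n_variants - 1`.
#' @param missing_rate fraction of cross-control genotype calls set to
#'   missing (exercises the missing-call policy; default 0).
#' @param pedigree_depth generations of proband ancestry emitted.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_case = 1L, n_breed_controls = 43L,
                       n_cross_controls = 176L, n_bank_genomes = 648L,
                       n_breeds = 50L, n_variants = 500L, n_genes = 60L,
                       planted = list(
                         gene = "BBS2", chrom = "2", pos = 59693737L,
                         ref = "G", alt = "C",
                         consequence = "missense_variant",
                         cds_pos = 1222L, sift = 0.03
                       ),
                       carrier_freq_in_breed = 0.1,
                       het_rate_controls = 0.15,
                       decoys = NULL, missing_rate = 0,
                       pedigree_depth = 3L) {
  if (n_case != 1L) stop("config error: exactly one case is supported")
  counts <- c(n_breed_controls, n_cross_controls, n_bank_genomes, n_breeds,
              n_variants, n_genes)
  if (any(counts < 0)) stop("config error: counts must be >= 0")
  rates <- c(carrier_freq_in_breed, het_rate_controls, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("config error: rates must lie in [0, 1]")
  if (carrier_freq_in_breed > 0 && n_breed_controls == 0) {
    stop("config error: carrier_freq_in_breed > 0 requires breed controls")
  }
  if (is.null(decoys)) {
    n_dec <- n_variants - 1L
    prop <- c(
      low_effect = 0.50, case_not_hom = 0.24, control_hom = 0.12,
      unplaced = 0.04, bank_carrier = 0.04, sift_tolerated = 0.03,
      no_keyword = 0.03
    )
    decoys <- stats::setNames(as.integer(pmax(floor(n_dec * prop), 1)), names(prop))
    decoys["low_effect"] <- decoys[["low_effect"]] + (n_dec - sum(decoys))
    if (decoys[["low_effect"]] < 0) stop("config error: n_variants too small for decoy classes")
  }
  needed <- c("low_effect", "case_not_hom", "control_hom", "unplaced",
              "bank_carrier", "sift_tolerated", "no_keyword")
  if (!setequal(names(decoys), needed)) {
    stop("config error: decoys must be named exactly: ", paste(needed, collapse = ", "))
  }
  if (sum(decoys) + 1L != n_variants) {
    stop("config error: decoy counts plus the planted variant must equal n_variants")
  }
  structure(
    list(
      seed = as.integer(seed), n_case = 1L,
      n_breed_controls = as.integer(n_breed_controls),
      n_cross_controls = as.integer(n_cross_controls),
      n_bank_genomes = as.integer(n_bank_genomes),
      n_breeds = as.integer(n_breeds), n_variants = as.integer(n_variants),
      n_genes = as.integer(n_genes), planted = planted,
      carrier_freq_in_breed = carrier_freq_in_breed,
      het_rate_controls = het_rate_controls,
      decoys = vapply(decoys[needed], as.integer, integer(1)),
      missing_rate = missing_rate,
      pedigree_depth = as.integer(pedigree_depth)
    ),
    class = "sim_config"
  )
}

CASE_BREED <- "Shetland Sheepdog"

# chromosome sort key: autosomes numerically, X, then unplaced contigs
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.integer(chrom))
  rank <- ifelse(!is.na(n), n, ifelse(chrom == "X", 100L, 200L))
  rank
}

#' Generate a synthetic cohort with a planted causal variant
#'
#' Writes, under `dir`: `cohort.vcf` (case + cross-breed controls),
#' `manifest.tsv`, `pedigree.tsv`, `bank.tsv`, `control_calls.tsv` (aged
#' breed-matched controls), `gene_phenotypes.tsv`, `symbol_map.tsv` and
#' `truth.tsv` (per-variant ground-truth class and the funnel stage
#' expected to remove it). The planted variant is homozygous in the case,
#' at most heterozygous in breed-matched controls, and absent from
#' cross-breed controls and the bank, so it survives the default funnel;
#' every decoy class violates exactly one criterion. Output is
#' deterministic: the same config yields byte-identical files.
#'
#' @param cfg a [sim_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list of file `paths`, the `truth` data.frame, the
#'   planted-gene [gene_model()], and the config.
#' @export
generate_cohort <- function(cfg, dir = tempfile("cohort")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  other_breeds <- sprintf("Breed%03d", seq_len(cfg$n_breeds))
  high_terms <- c("stop_gained", "frameshift_variant", "splice_donor_variant",
                  "splice_acceptor_variant", "inframe_deletion", "missense_variant")
  low_terms <- c("intron_variant", "synonymous_variant", "intergenic_variant",
                 "5_prime_UTR_variant", "3_prime_UTR_variant",
                 "upstream_gene_variant", "downstream_gene_variant")

  # gene namespace: keyword-bearing genes (some as unmapped-style stable
  # ids resolved through the symbol map), plus reserved no-keyword genes
  n_bland <- max(2L, ceiling(cfg$n_genes * 0.15))
  n_kw <- cfg$n_genes - n_bland
  n_ens <- floor(n_kw / 3)
  kw_plain <- sprintf("GENE%04d", seq_len(n_kw - n_ens))
  ens_ids <- sprintf("ENSCAFG%011d", seq_len(n_ens))
  ens_syms <- sprintf("ORTH%04d", seq_len(n_ens))
  bland <- sprintf("BLAND%04d", seq_len(n_bland))

  classes <- c("planted", rep(names(cfg$decoys), cfg$decoys))
  n <- length(classes)
  ord <- sample.int(n) # scatter classes across the genome
  classes <- classes[ord]

  chrom <- character(n)
  pos <- integer(n)
  autosomes <- as.character(1:38)
  is_unplaced <- classes == "unplaced"
  chrom[!is_unplaced] <- sample(autosomes, sum(!is_unplaced), replace = TRUE)
  chrom[is_unplaced] <- sprintf("chrUn_%05d", sample.int(99999, sum(is_unplaced)))
  pos <- sample.int(10^8, n) # unique genome-wide, avoids the planted locus
  pos[pos == cfg$planted$pos] <- cfg$planted$pos + 1L

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  gene <- character(n)
  consequence <- character(n)
  sift <- rep(NA_real_, n)
  kw_pool <- c(kw_plain, ens_ids)
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "low_effect") {
      gene[i] <- sample(kw_pool, 1)
      consequence[i] <- sample(low_terms, 1)
    } else if (cl == "no_keyword") {
      gene[i] <- sample(bland, 1)
      consequence[i] <- sample(high_terms, 1)
    } else {
      gene[i] <- sample(kw_pool, 1)
      consequence[i] <- if (cl == "sift_tolerated") "missense_variant" else sample(high_terms, 1)
    }
    if (consequence[i] == "missense_variant") {
      sift[i] <- if (cl == "sift_tolerated") round(stats::runif(1, 0.2, 0.9), 2)
        else round(stats::runif(1, 0, 0.04), 2)
    }
  }

  # planted variant
  pl <- which(classes == "planted")
  chrom[pl] <- cfg$planted$chrom
  pos[pl] <- cfg$planted$pos
  ref[pl] <- cfg$planted$ref
  alt[pl] <- cfg$planted$alt
  gene[pl] <- cfg$planted$gene
  consequence[pl] <- cfg$planted$consequence
  sift[pl] <- cfg$planted$sift

  # genotypes: case + cross-breed controls
  case_id <- "CASE1"
  ctrl_ids <- sprintf("CTRL%03d", seq_len(cfg$n_cross_controls))
  geno <- matrix(0L, nrow = n, ncol = 1L + cfg$n_cross_controls,
                 dimnames = list(NULL, c(case_id, ctrl_ids)))
  for (i in seq_len(n)) {
    cl <- classes[i]
    geno[i, case_id] <- if (cl == "case_not_hom") sample(0:1, 1) else 2L
    clean <- cl %in% c("planted", "bank_carrier", "sift_tolerated", "no_keyword")
    if (!clean && cfg$n_cross_controls > 0) {
      geno[i, -1L] <- stats::rbinom(cfg$n_cross_controls, 1L, cfg$het_rate_controls)
    }
    if (cl == "control_hom" && cfg$n_cross_controls > 0) {
      hom_in <- sample.int(cfg$n_cross_controls, sample(1:min(3L, cfg$n_cross_controls), 1))
      geno[i, 1L + hom_in] <- 2L
    }
  }
  if (cfg$missing_rate > 0 && cfg$n_cross_controls > 0) {
    ctrl_part <- geno[, -1L, drop = FALSE]
    drop <- stats::runif(length(ctrl_part)) < cfg$missing_rate & ctrl_part < 2L
    ctrl_part[drop] <- NA_integer_
    geno[, -1L] <- ctrl_part
  }

  o <- order(chrom_rank(chrom), chrom, pos)
  vs <- variant_set(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
               consequence = consequence, sift = sift,
               stringsAsFactors = FALSE)[o, ],
    geno[o, , drop = FALSE]
  )
  classes <- classes[o]

  stage_of <- c(
    planted = "retained", low_effect = "high_effect",
    case_not_hom = "recessive", control_hom = "recessive",
    unplaced = "unplaced", bank_carrier = "bank_absence",
    sift_tolerated = "sift", no_keyword = "keyword"
  )
  truth <- data.frame(
    key = vs_keys(vs), class = classes,
    stage = unname(stage_of[classes]), stringsAsFactors = FALSE
  )

  # genome bank: 3 genomes of the case breed, the rest cycling other breeds
  bank_ids <- sprintf("BANK%04d", seq_len(cfg$n_bank_genomes))
  bank_breeds <- c(
    rep(CASE_BREED, min(3L, cfg$n_bank_genomes)),
    other_breeds[(seq_len(max(0L, cfg$n_bank_genomes - 3L)) - 1L) %% cfg$n_breeds + 1L]
  )
  non_exempt <- which(bank_breeds != CASE_BREED)
  bank_rows <- list(data.frame(
    genome_id = bank_ids, breed = bank_breeds, chrom = "", pos = "",
    ref = "", alt = "", gt = "", stringsAsFactors = FALSE
  ))
  for (i in which(classes == "bank_carrier")) {
    k <- sample(non_exempt, sample(1:3, 1))
    bank_rows[[length(bank_rows) + 1L]] <- data.frame(
      genome_id = bank_ids[k], breed = bank_breeds[k],
      chrom = vs$variants$chrom[i], pos = as.character(vs$variants$pos[i]),
      ref = vs$variants$ref[i], alt = vs$variants$alt[i], gt = "0/1",
      stringsAsFactors = FALSE
    )
  }
  bank_tab <- do.call(rbind, bank_rows)

  # aged breed-matched controls: carriers at carrier_freq, never hom-alt
  bc_ids <- sprintf("SSC%03d", seq_len(cfg$n_breed_controls))
  mined <- which(classes %in% c("planted", "bank_carrier", "sift_tolerated", "no_keyword"))
  cc_rows <- lapply(mined, function(i) {
    g <- stats::rbinom(cfg$n_breed_controls, 1L, cfg$carrier_freq_in_breed)
    data.frame(
      sample_id = bc_ids, chrom = vs$variants$chrom[i],
      pos = vs$variants$pos[i], ref = vs$variants$ref[i],
      alt = vs$variants$alt[i], gt = c("hom_ref", "het")[g + 1L],
      stringsAsFactors = FALSE
    )
  })
  control_calls <- do.call(rbind, cc_rows)

  # manifest
  ctrl_breeds <- other_breeds[(seq_len(cfg$n_cross_controls) - 1L) %% cfg$n_breeds + 1L]
  manifest <- rbind(
    data.frame(id = case_id, breed = CASE_BREED, cohort = "wgs",
               phenotype = "case", age_years = 8.7, role = "proband",
               stringsAsFactors = FALSE),
    data.frame(id = ctrl_ids, breed = ctrl_breeds, cohort = "wgs",
               phenotype = "control", age_years = NA_real_,
               role = "cross_genome_control", stringsAsFactors = FALSE),
    data.frame(id = bc_ids, breed = CASE_BREED, cohort = "aged_controls",
               phenotype = "control",
               age_years = 8 + (seq_len(cfg$n_breed_controls) %% 7),
               role = "breed_control", stringsAsFactors = FALSE)
  )

  # proband ancestry chain to the configured depth
  ped_rows <- data.frame(id = case_id, sire = "SIRE_G1", dam = "DAM_G1",
                         stringsAsFactors = FALSE)
  for (d in seq_len(cfg$pedigree_depth - 1L)) {
    ped_rows <- rbind(ped_rows, data.frame(
      id = c(sprintf("SIRE_G%d", d), sprintf("DAM_G%d", d)),
      sire = c(sprintf("SIRE_G%d", d + 1L), ""),
      dam = c(sprintf("DAM_G%d", d + 1L), ""),
      stringsAsFactors = FALSE
    ))
  }

  # gene -> phenotype text (keyed by symbol) and id -> symbol map
  all_syms <- c(cfg$planted$gene, kw_plain, ens_syms, bland)
  gp <- data.frame(
    gene = all_syms,
    phenotype_text = c(
      "Bardet-Biedl syndrome; retinal degeneration, obesity, renal anomalies",
      rep("Progressive retinal degeneration with photoreceptor loss", length(kw_plain)),
      rep("Retinitis pigmentosa-like rod-cone dystrophy", length(ens_syms)),
      rep("Skeletal muscle development and glycogen storage", length(bland))
    ),
    stringsAsFactors = FALSE
  )
  smap <- data.frame(
    id = c(cfg$planted$gene, kw_plain, ens_ids, bland),
    symbol = c(cfg$planted$gene, kw_plain, ens_syms, bland),
    stringsAsFactors = FALSE
  )

  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    manifest = file.path(dir, "manifest.tsv"),
    pedigree = file.path(dir, "pedigree.tsv"),
    bank = file.path(dir, "bank.tsv"),
    control_calls = file.path(dir, "control_calls.tsv"),
    gene_phenotypes = file.path(dir, "gene_phenotypes.tsv"),
    symbol_map = file.path(dir, "symbol_map.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_vcf(vs, paths$vcf)
  write_tsv <- function(x, p) {
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(manifest, paths$manifest)
  write_tsv(ped_rows, paths$pedigree)
  write_tsv(bank_tab, paths$bank)
  write_tsv(control_calls, paths$control_calls)
  write_tsv(gp, paths$gene_phenotypes)
  write_tsv(smap, paths$symbol_map)
  write_tsv(truth, paths$truth)

  invisible(list(paths = paths, truth = truth, config = cfg,
                 gene_model = synthetic_bbs2_model()))
}
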