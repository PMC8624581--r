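# Shared fixture builders and independent brute-force oracles.
# Oracles are written as plain per-variant / per-genome loops so they stay
# independent of the vectorized implementation paths they check.

# random variant set: genotype codes drawn uniformly from 0/1/2 (plus NA
# at missing_rate), genes/consequences cycled deterministically
rand_variant_set <- function(n_var, sample_ids, missing_rate = 0) {
  chroms <- as.character(sample(1:38, n_var, replace = TRUE))
  v <- data.frame(
    chrom = chroms,
    pos = sample.int(10^7, n_var),
    ref = sample(c("A", "C", "G", "T"), n_var, replace = TRUE),
    alt = "N",
    gene = sprintf("G%03d", (seq_len(n_var) - 1L) %% 25L + 1L),
    consequence = rep(c("missense_variant", "intron_variant"), length.out = n_var),
    stringsAsFactors = FALSE
  )
  v$alt <- ifelse(v$ref == "A", "T", "A")
  g <- matrix(sample(0:2, n_var * length(sample_ids), replace = TRUE),
              nrow = n_var, dimnames = list(NULL, sample_ids))
  if (missing_rate > 0) {
    g[runif(length(g)) < missing_rate] <- NA_integer_
  }
  variant_set(v, g)
}

# independent recessive-scan oracle: explicit loop over variants and samples
brute_recessive_keys <- function(vs, case_id, control_ids, missing_vetoes = FALSE) {
  keep <- character(0)
  for (i in seq_len(n_variants(vs))) {
    case <- vs$geno[i, case_id]
    if (is.na(case) || case != 2L) next
    vetoed <- FALSE
    for (s in control_ids) {
      g <- vs$geno[i, s]
      if (is.na(g)) {
        if (missing_vetoes) vetoed <- TRUE
      } else if (g == 2L) {
        vetoed <- TRUE
      }
    }
    if (!vetoed) keep <- c(keep, vs$variants$key[i])
  }
  keep
}

# random sparse genome bank over the keys of a variant set
rand_bank <- function(vs, n_genomes, breeds, carrier_rate = 0.1) {
  ids <- sprintf("BG%03d", seq_len(n_genomes))
  br <- sample(breeds, n_genomes, replace = TRUE)
  rows <- list(data.frame(genome_id = ids, breed = br, chrom = "", pos = "",
                          ref = "", alt = "", gt = "", stringsAsFactors = FALSE))
  for (i in seq_len(n_variants(vs))) {
    carriers <- which(runif(n_genomes) < carrier_rate)
    if (length(carriers) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = ids[carriers], breed = br[carriers],
      chrom = vs$variants$chrom[i], pos = as.character(vs$variants$pos[i]),
      ref = vs$variants$ref[i], alt = vs$variants$alt[i],
      gt = sample(c("0/1", "1/1"), length(carriers), replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  read_genome_bank(f)
}

# brute-force bank scans: loop per variant over every recorded call
brute_bank_keys <- function(vs, bank, exempt_breeds, mode = c("absence", "hom")) {
  mode <- match.arg(mode)
  call_key <- bank$calls$key
  call_breed <- bank$calls$breed
  call_code <- bank$calls$code
  keep <- character(0)
  for (i in seq_len(n_variants(vs))) {
    key <- vs$variants$key[i]
    bad <- FALSE
    for (r in seq_along(call_key)) {
      if (call_key[r] != key) next
      if (call_breed[r] %in% exempt_breeds) next
      if (is.na(call_code[r])) next
      if (mode == "absence" && call_code[r] >= 1L) bad <- TRUE
      if (mode == "hom" && call_code[r] == 2L) bad <- TRUE
    }
    if (!bad) keep <- c(keep, key)
  }
  keep
}

# small generator config so module tests stay fast; the full-scale default
# config is exercised in the acceptance suite
small_sim_config <- function(seed = 1L, ...) {
  sim_config(
    seed = seed, n_breed_controls = 10L, n_cross_controls = 20L,
    n_bank_genomes = 30L, n_breeds = 8L, n_variants = 80L, n_genes = 20L,
    ...
  )
}

run_small_pipeline <- function(seed = 1L, quiet = TRUE, mutate_vcf = NULL) {
  sim <- generate_cohort(small_sim_config(seed))
  if (!is.null(mutate_vcf)) mutate_vcf(sim$paths$vcf)
  rep <- run_pipeline(sim$paths, gene_models = list(BBS2 = sim$gene_model),
                      quiet = quiet)
  list(sim = sim, report = rep)
}
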