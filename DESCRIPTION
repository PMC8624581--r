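Package: vcfunnel
Title: Case/Control Variant-Prioritization Funnel for Recessive Disease Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing candidate causal variants from a multi-sample
    whole-genome callset under a Mendelian recessive model: consequence-based
    effect scoring, case/control segregation filters, genome-bank (cross-breed
    panel) filtering, gene-candidacy ranking by phenotype keywords, gene-panel
    variant extraction, post-funnel exclusion by genotyping aged breed-matched
    controls, pedigree-aware population frequency reporting, and HGVS-style
    coding/protein change annotation. Ships a deterministic synthetic-cohort
    generator with a planted causal variant and labelled decoys so every funnel
    stage is testable offline, plus packaged genotype-count fixtures for a worked
    canine retinal-degeneration example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
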