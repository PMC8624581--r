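---
title: "Prioritizing a recessive causal variant from a case/control genome callset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing a recessive causal variant from a case/control genome callset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfunnel)
```

## The problem

A single affected individual (the proband) of one breed is whole-genome
sequenced; its variants are called jointly with many control genomes of
other breeds that were sequenced for unrelated studies. For a fully
penetrant autosomal-recessive disease that is private to the proband's
breed, the causal variant must be (i) functionally plausible, (ii)
homozygous in the proband and homozygous in no healthy genome, (iii)
absent from large multi-breed genome banks, and (iv) located in a gene
whose known phenotype spectrum is compatible with the disease. `vcfunnel`
implements that prioritization as an auditable funnel of filters over a
multi-sample VCF, ending with genotyping of the surviving candidates in
aged, clinically clear, breed-matched controls and protein-level
annotation of what remains.

The worked example throughout the package is a canine progressive retinal
atrophy (PRA) analysis in the Shetland Sheepdog, where the funnel isolates
a missense variant in the ciliopathy gene *BBS2* (c.1222G>C, p.Ala408Pro)
and population screening shows it is rare and breed-private.

## The funnel

Stages run in a serial trunk followed by two parallel branches:

1. **Known-variant screen.** The proband's genotype is reported at every
   previously published disease locus; a homozygous alternate call at any
   of them flags the run, since the disease would then likely not be novel.
2. **Effect scoring.** Each variant's consequence terms (VEP-style
   vocabulary) map to an integer severity score 0–5 through an overridable
   table; a variant's score is the maximum over its terms
   (worst-consequence convention). Scores 4–5 — truncating, splice-site,
   missense, in-frame indel classes — are "high effect" and pass.
3. **Recessive segregation.** Keep variants homozygous-alternate in the
   case with no homozygous-alternate control. Heterozygous controls pass:
   they are expected carriers. An X-linked branch (dominant and recessive)
   is computed from the same high-effect set and reported alongside, as a
   side analysis rather than a trunk stage.
4. **Unplaced-contig exclusion.** Variants on `chrUn_*`-style contigs are
   removed; annotation and downstream genotyping are unreliable there.
5. **Branch A — genome-bank absence.** Keep variants carried by *no*
   non-exempt bank genome. Breeds closely related to the case breed can be
   exempted, because a breed-private recessive may legitimately segregate
   in them.
6. **Branch B — gene candidacy.** SIFT-tolerated variants are removed
   (threshold 0.05, the tool's conventional boundary; unscored variants
   are kept — absence of a prediction is not evidence of tolerance), then
   variants homozygous in any non-exempt bank genome, then variants whose
   gene cannot be resolved to a symbol through the supplied id-to-symbol
   table, and finally variants whose gene's phenotype text matches no
   keyword of the disease keyword list.
7. **Intersection and mining.** The branch survivors are intersected and
   genotyped in aged (default ≥ 8 years), clinically clear, breed-matched
   controls: one homozygous control excludes a candidate; candidates with
   no successful control call are carried as `unresolved_assay_failure`,
   ranked below retained ones. Retained single-nucleotide candidates with
   a gene model available are annotated at protein level.

Every input variant appears exactly once in the report's accounting with a
single first-cause stage, and each stage's output is an order-preserving
subset of its input, so per-stage counts audit the run.

### Design choices in ambiguous corners

* **Control-side recessive condition.** The filter requires that controls
  are *not* homozygous for the alternate allele (carriers allowed). A
  literal "het or hom-alt in all controls" reading would demand every
  control carry the allele, which is incompatible with subsequent
  genome-bank absence filtering; the implemented rule is the standard
  intent for a rare recessive.
* **Missing genotypes** are a distinct state, never treated as hom-ref,
  and never satisfy a filter predicate. A missing control call does not
  veto retention by default (a missing call is not evidence of
  homozygosity); `missing_vetoes = TRUE` gives the conservative
  alternative. Missing calls are excluded from allele-frequency
  denominators, not imputed.
* **"Multiple cross-breed homozygotes"** in the bank-homozygosity filter
  is operationalized as ≥ 1 by default (`min_hom_genomes`): for a fully
  penetrant breed-private recessive, any healthy cross-breed homozygote is
  disqualifying.
* **Branch merging.** The bank-absence and candidacy branches are computed
  and reported side by side, then intersected for the final candidate set;
  neither is privileged, and each branch's counts remain visible.
* **X hemizygosity.** Male X calls are caller-dependent in diploid
  encodings, so any genotype carrying the alternate allele on X counts as
  carriage.
* **Keyword matching** is word-boundary and case-insensitive by default
  (`cilia` does not match `ciliary`); a substring mode exists. Matching is
  over locally supplied gene-to-phenotype text only — no ontology
  expansion, no live database queries.
* **Panel extraction** mirrors `grep -wE` semantics: whole-word,
  case-sensitive matching of the gene field against the panel's canonical
  names and synonyms (the shipped 21-gene Bardet–Biedl panel carries
  `BBS8`/`TTC8` and `BBIP1`/`BBIP10` as synonym pairs).
* **Effect-score table.** The shipped default places a retained start
  codon (`start_retained_variant`) at 3 with the synonymous classes, since
  a retained start is consequence-neutral. The table is data
  (`effect_scores.tsv`), not code.

## Pedigree-aware population screening

`screen_population()` aggregates per-individual genotype calls into
per-cohort, per-phenotype and per-breed-group tables with allele
frequencies `(2·hom + het) / (2·n)`. "Third-generation relatives" of the
proband are individuals sharing an ancestor within three parent-links of
both (covering siblings, half-siblings and cousins up to
great-grandparental lines); the depth is a parameter, since the term has
no universal definition. The relative-excluded frequency removes the
proband *itself* together with its relatives: the excluded set is the
ascertainment cluster, and in the worked example this is what reconciles
the homozygote counts (7 overall, 4 after exclusion — the proband and its
two affected littermates are the three removed homozygotes). Display
rounding is half-up to 3 decimals (so 31/1010 prints as 0.031); internal
values are unrounded.

```{r}
ft <- fixture_tables()
ft$breeds[, 1:6]
```

The packaged fixture is per-individual: 1386 genotyped canids (505 of the
case breed across five genotyping cohorts, 15 crossbreeds, 8 wolves, 858
dogs of 154 other breeds) with a pedigree linking the proband, two
affected littermates and four heterozygous relatives. Only the *margins*
of the published tables are known; the joint cohort × phenotype ×
genotype assignment of individuals is the package's own synthetic
construction, chosen to be consistent with every published margin.

## Coding annotation

`gene_model()` holds ordered exons plus the spliced CDS;
`genomic_to_cds()` / `cds_to_genomic()` are strand-aware inverses on
exonic positions, `cds_to_codon()` is `ceiling(pos/3)` with the in-codon
offset, and `annotate_substitution()` checks the supplied reference base
against the model (reference discordance is an error), translates the
affected codon with the standard genetic code, and emits HGVS-style
protein notation (`p.Ala408Pro`; synonymous changes as `p.Ala408=`;
parenthesized predicted-style output is optional). Only substitutions are
annotated at protein level.

The real canine *BBS2* CDS is not bundled; `synthetic_bbs2_model()` is a
deterministic synthetic stand-in with the same protein length (715
residues), `GCA` at codon 408, and exon coordinates arranged so that
chromosome 2 position 59,693,737 maps to c.1222 in exon 11. Conclusions
about the real gene's sequence cannot be drawn from it; it exists so the
coordinate arithmetic and the worked example are reproducible offline.

## The synthetic cohort generator

`generate_cohort()` emits everything a funnel run consumes: a
multi-sample VCF (case plus cross-breed controls), manifest, pedigree,
sparse genome-bank table, breed-matched control calls, gene-to-phenotype
map, id-to-symbol map, and a ground-truth table. Defaults mirror the
worked example's study design — 1 case versus 176 cross-breed control
genomes, a 648-genome bank including 3 genomes of the case breed, 43 aged
breed-matched controls — at a desk-scale variant count of 500 (a
genome-scale callset of ~27.6 M variants is neither necessary nor
practical for validating filter logic; the funnel operates per variant).

The planted causal variant is homozygous in the case, at most
heterozygous in breed-matched controls (carrier frequency 0.10 by
default), and absent from cross-breed controls and the bank. Decoys each
violate exactly one criterion — low effect score, case not homozygous, a
homozygous control, unplaced contig, bank carriage, SIFT-tolerated,
no keyword match — in default proportions 50/24/12/4/4/3/3 percent of the
decoy budget, scattered over autosomes 1–38 (plus `chrUn_*` contigs for
the unplaced class). Genotypes are generated directly; read-level
simulation, linkage structure and demography are deliberately out of
scope. Consequently, passing tests demonstrate the correctness of the
filtering logic under the stated genotype model, not robustness to
caller artifacts, annotation errors or population structure in real data.

Generation is deterministic: one seed fixes every file byte-for-byte.
Missingness can be injected at a configured rate to exercise the
missing-call policy.

## Problem sizes used in the test suite

Module tests run the generator at a reduced design (20 cross-breed
controls, 30 bank genomes, 80 variants) chosen to exercise every decoy
class with at least one variant. The end-to-end checks run the full
default design across 20 seeds, and the brute-force equivalence checks
run 1000 randomized 100-variant × 20-sample trials against independent
per-variant/per-genome loop oracles. These sizes are the package's
validation design; all scale linearly for users who wish to enlarge them.

## Known limitations

* Bi-allelic records only after splitting; genotype likelihoods, phasing
  and structural variants are out of scope.
* Compound-heterozygote and de novo models are not implemented; the
  funnel assumes a single fully penetrant recessive (or X-linked) locus.
* Consequence terms and SIFT scores are consumed as annotations, never
  predicted.
* The generator's decoys violate exactly one criterion each; real
  variants can fail several filters at once, which the accounting
  attributes to the first stage reached.
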