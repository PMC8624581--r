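# vcfunnel

Prioritization of candidate causal variants for a Mendelian recessive
disease from a multi-sample whole-genome callset, built for the classic
single-proband design used in veterinary and model-organism genetics: one
affected genome is filtered against many control genomes of other
breeds/populations, a multi-breed genome bank, and a panel of aged,
clinically clear, breed-matched controls.

The package is aimed at analysts running (or auditing) gene-discovery
funnels: every filter is an explicit, order-preserving operation over a
variant set, and the pipeline's report accounts for every input variant
with a single first-cause exclusion stage.

## The method

For a fully penetrant autosomal-recessive, breed-private variant, the
funnel retains variant *v* with genotype `g(s, v)` ∈ {0, 1, 2} copies of
the alternate allele iff:

1. **effect score** `max over consequence terms of score(term)` ∈ {4, 5}
   (truncating / splice / missense / in-frame classes, user-overridable
   table);
2. **segregation** `g(case, v) = 2` and `g(c, v) ≠ 2` for every control
   genome `c` (carriers permitted; missing calls never satisfy nor veto);
3. **placement** — not on an unplaced contig;
4. **branch A (bank absence)** — no non-exempt bank genome with
   `g ≥ 1`;
5. **branch B (candidacy)** — SIFT ≤ 0.05 or unscored; no non-exempt
   bank homozygote; gene resolvable to a symbol; gene phenotype text
   matches a disease keyword (word-boundary, case-insensitive);
6. **mining** — no aged breed-matched control with `g = 2`.

Branches A and B are intersected; survivors are annotated at protein
level (`c.` position → codon `⌈pos/3⌉` → HGVS `p.` change via the
standard genetic code). Population screening then reports per-cohort /
per-phenotype / per-breed genotype counts and allele frequencies
`(2·hom + het) / (2·n)`, including an estimate with the proband's
relatives within three parent-links excluded.

## Worked example

Generate a synthetic cohort at the worked example's study design (1 case
vs 176 cross-breed control genomes, a 648-genome bank, 43 aged
breed-matched controls, 500 variants with one planted causal missense
variant and labelled decoys), then run the funnel:

```r
library(vcfunnel)
sim <- generate_cohort(sim_config(seed = 1))
rep <- run_pipeline(sim$paths, gene_models = list(BBS2 = sim$gene_model))
rep
#> Variant-prioritization funnel
#> case: CASE1 ( Shetland Sheepdog )
#>
#>        branch               stage n_in n_out
#>         trunk         high_effect  500   245
#>         trunk           recessive  245    67
#>         trunk            unplaced   67    48
#>      x_linked          x_dominant  245     0
#>      x_linked         x_recessive  245     0
#>  bank_absence        bank_absence   48    29
#>     candidacy                sift   48    34
#>     candidacy   bank_homozygosity   34    34
#>     candidacy  identifier_mapping   34    34
#>     candidacy             keyword   34    20
#>         final branch_intersection   48     1
#>         final  control_genotyping    1     1
#>
#> final candidates:
#>             key gene   status
#>  2:59693737:G:C BBS2 retained
#>
#> protein-level annotation:
#>             key gene cds_pos    hgvs_c      hgvs_p consequence
#>  2:59693737:G:C BBS2    1222 c.1222G>C p.Ala408Pro    missense
```

The trunk narrows 500 variants to 48; the bank-absence and candidacy
branches independently narrow those to 29 and 20; their intersection is
the single planted variant, which survives control genotyping and is
annotated as an alanine-to-proline missense change at codon 408
(`⌈1222/3⌉ = 408`). The report's `accounting` table attributes every one
of the 499 decoys to exactly the stage built to remove it.

Population screening on the packaged 1386-canid fixture:

```r
fp <- fixture_population()
screen_population(fp$calls, fp$proband, fp$pedigree)
#> breed groups:
#>                                   group n_hom_alt n_het n_hom_ref total allele_frequency
#>                       Shetland Sheepdog         7    17       481   505            0.031
#>  Shetland Sheepdog (relatives excluded)         4    13       481   498            0.021
#>                             crossbreeds         0     0        15    15            0.000
#>                                  wolves         0     0         8     8            0.000
#>                        154 other breeds         0     0       858   858            0.000
```

The alternate allele appears in no other breed (`breed_private: TRUE`);
the case-breed frequency is 0.031, falling to 0.021 once the proband and
its relatives within three parent-links (its two affected littermates and
four heterozygous cousins) are excluded.

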