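# tp53pancan

TP53 is the most frequently mutated gene across human cancers, and its
loss reshapes the tumor transcriptome: genes normally repressed by p53
rise in TP53-mutated tumors, truncating mutations depress TP53's own
transcript while some missense mutants accumulate, and mutant-TP53 cells
come to depend on genes they did not need before — candidate synthetic-
lethality (SL) partners and drug targets. `tp53pancan` is an R package
for running this whole analysis arc on multi-cancer cohorts: mutation
tables (MAF), tumor/normal expression matrices, clinical endpoints and a
pharmacogenomic IC50 screen, for analysts working with TCGA-style data
or any cohort in the same shapes.

## What it computes

**Mutation profiling.** Per-cancer-type mutation rates (fraction of
sequenced samples with a non-silent record), min-rank gene ranking with
optional exclusion of extreme-length genes, proportions of the eight
variant classes (missense, nonsense, frame-shift ins/del, in-frame
ins/del, silent, splice-site), and Fisher's exact association between
TP53 status and binned clinical phenotypes (stage I–II vs III–IV, T1–2
vs T3–4, N0 vs N1–3, M0 vs M1, gender, race).

**The gene-class calculus.** For each cancer type, per-gene
pooled-variance t-tests on log2 expression with Benjamini-Hochberg FDR,
fold change computed as `2^(difference of log2 group means)`:

* `MW` — higher in TP53-mutated than TP53-wildtype tumors (FC > 1.5, FDR < 0.05)
* `WN` / `WN2` — higher in wildtype tumors than normals (FC > 1.5 / > 1.2)
* `MN` — higher in mutated tumors than normals (FC > 1.5)
* `MWN = MW ∩ WN` (mutated > wildtype > normal pattern)
* `MSN = MN ∖ WN2` (elevated specifically in mutated tumors)
* SL candidates = `MW ∩ MSN`, cross-validated against compounds with
  significantly lower IC50 in TP53-mutated cell lines (p < 0.05,
  FDR < 0.2, mutant-selective direction required)

plus recurrence filtering across cancer types, TP53 co-expression sets
(PCOR/NCOR: correlated with TP53 in tumors at FDR < 0.05 but not in
normals), cytoband over-representation, TP53 expression patterns across
truncating/non-truncating/wildtype/normal groups, and Kaplan-Meier /
log-rank survival comparisons by mutation status, median-split TP53
expression, or both combined.

**Synthetic cohorts.** `generate_cohort()` / `generate_pharmaco()` draw
multi-cancer cohorts with fully known planted structure (effect sizes,
mutation mixtures, survival hazards, sensitised compounds), so every
stage is testable without downloads. See the methods vignette
(`vignettes/tp53pancan-methods.Rmd`) for the model and its limits.

## Worked example

```r
library(tp53pancan)

cfg <- generator_config(n_types = 1, seed = 1)
cohort <- generate_cohort(cfg)

mutation_rates(cohort$mutations)
#> # A tibble: 1 × 5
#>   cancer_type n_samples n_mutated  rate percent
#>   <chr>           <int>     <int> <dbl>   <dbl>
#> 1 T01               100        50   0.5      50

cls <- derive_gene_classes(cohort$studies$T01)
cls
#> <gene_class_sets> T01
#>   MW     101 gene(s)
#>   WN     100 gene(s)
#>   WN2    100 gene(s)
#>   MN     149 gene(s)
#>   MWN     46 gene(s)
#>   MSN     53 gene(s)

cand <- sl_candidates(list(T01 = cls))
ph <- generate_pharmaco(cfg, cohort$truth)
screen <- ic50_screen(ph$screen)
flagged_compounds(screen)
#> [1] "CP01" "CP02" "CP03" "CP04" "CP05"

head(cross_validate_candidates(cand, ph$screen, flagged_compounds(screen)), 3)
#> # A tibble: 3 × 3
#>   gene  compound cancer_types
#>   <chr> <chr>    <chr>
#> 1 G0101 CP01     T01
#> 2 G0102 CP02     T01
#> 3 G0103 CP03     T01
```

Reading the output: half of the 100 tumors carry a non-silent TP53
mutation (the generator's planted fraction). The class sizes reflect the
planted structure — the 101-gene MW set is the 50 planted MW genes plus
the 50 planted SL genes (both genuinely higher in mutated tumors) with
one false positive; MSN captures the mutant-specific genes and
`MW ∩ MSN` recovers 92% of the planted SL set on this seed. All five
compounds with a planted −1 log-unit IC50 shift in TP53-mutated lines
are flagged, and each flagged compound's target is confirmed as an SL
candidate in the evidence table.

A command-line front end wrapping the same functions ships at
`inst/cli/tp53pancan` (subcommands `simulate`, `mutation-rates`,
`classes`, `coexpress`, `survival`, `sl-screen`, `ic50`).

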