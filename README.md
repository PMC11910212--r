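# regensig

Cross-species, cross-platform meta-analysis of regeneration transcriptomics
by rank aggregation.

## The problem

Skin-regeneration experiments that probe the same biology — wound-induced
hair neogenesis (WIHN) in high- versus low-regenerating mouse strains,
laser-rejuvenated versus baseline human skin, dsRNA (poly I:C)-stimulated
versus untreated human keratinocytes — are measured on different microarray
or sequencing platforms in different species. Signal values are not
comparable across platforms, but each experiment's *fold changes* are
internally consistent: the ratio of high-regeneration over low-regeneration
group means compares like with like. `regensig` implements the resulting
meta-analysis for anyone who wants a shared "regeneration signature" from k
such experiments:

1. update gene symbols to current nomenclature (alias table), map mouse
   genes to their human orthologs (HomoloGene/HCOP-style two-column table),
   and restrict to the **common universe** — the identical gene set present
   in every experiment after mapping (size U);
2. compute each gene's log2 fold change (probe sets collapsed to genes by
   their median), **rank** genes within each experiment from highest to
   lowest fold change (rank 1 = largest; ties get average ranks, so each
   rank table sums to U(U+1)/2);
3. **aggregate**: average each gene's rank across the k experiments,
   `r̄(g) = (1/k) Σᵢ rᵢ(g)`, and re-sort ascending;
4. extract **top-N signature lists** (per experiment, or from the aggregate
   ranking), intersect them (all 2^k − 1 Venn regions for k ≤ 3), and
   compare the central overlap with its independence expectation
   `U · Πᵢ (nᵢ/U)` and a seeded permutation null,
   `p = (1 + #{null ≥ obs}) / (M + 1)`;
5. test the overlap for **term enrichment** with one-sided Fisher's exact
   tests (hypergeometric tail) over a GMT term database, with
   Benjamini–Hochberg and Bonferroni adjustment.

A synthetic-study generator (`generate_study()`) plants a known signature
across simulated multi-platform, two-species experiments — complete with
probe multiplicity, outdated aliases, unmapped genes and mouse paralogs — so
every stage of the pipeline is verifiable at desk scale without downloads.

## Worked example

Simulate three experiments (one mouse, two human) over 2000 orthologous
genes with 20 planted signature genes at a 3-sigma log2 effect, take each
experiment's top-200 list, and intersect:

```r
library(regensig)

res <- run_pipeline(list(
  synthetic = list(U = 2000, k = 3, S = 20, delta = 3, sigma = 1, seed = 7),
  n_top = 200, n_perm = 10000
))
res
#> <regensig_result> 3 experiments, universe U = 1901, n_top = 200 (per_dataset mode)
#>   central overlap: 22 gene(s) (expected 2.21, permutation p = 0.0001)
#>   top enriched term: TERM000 (p = 1.64e-45)
#>   planted-signature recovery: recall 1.000, precision 0.909
```

The universe is 1901 genes rather than 2000 because the simulation, like
real data, leaves a fraction of mouse genes without an ortholog record; the
intersection removes them. All 20 planted genes land in the central overlap
(recall 1.0) alongside 2 bystanders (precision 0.909). Under independent
top-200 lists the expected three-way overlap is only
`1901 · (200/1901)³ ≈ 2.2`, and no permutation among 10,000 reached the
observed 22, so `p = 1/10001 = 0.0001`.

```r
tidy(res$overlap)
#> # A tibble: 7 × 4
#>   region                 pattern     n genes
#> 1 central                111        22 <chr [22]>
#> 2 human_03&mouse_01 only 011        11 <chr [11]>
#> 3 human_02&mouse_01 only 101        14 <chr [14]>
#> ...

head(tidy(res$enrichment), 3)
#> # A tibble: 3 × 6
#>   term_id term_name         n_term     a  p_value     p_bh
#> 1 TERM000 planted_signature     20    20 1.64e-45 3.43e-44
#> 2 TERM005 decoy_process_05      43     1 3.97e- 1 1
#> 3 TERM001 decoy_process_01      40     0 1        1
```

The planted term contains all 20 of its genes in the 22-gene overlap and
dominates the decoy terms by ~44 orders of magnitude.

Real studies run through the same entry point with file-backed experiment
declarations (expression TSVs with `probe_id`, `gene_symbol` and sample
columns; a two-column design TSV; alias/ortholog TSVs; a GMT term file) —
see `?run_pipeline` and `?validate_config`. Results expose broom-style
`tidy()`/`glance()` and ggplot2 `autoplot()` methods, and `out_dir` writes
every table as TSV with a JSON provenance sidecar (config hash, seed,
tie-break events).

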