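---
title: "Methods: cross-species signature meta-analysis by rank aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species signature meta-analysis by rank aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regensig)
```

## The model

`regensig` asks whether independent two-group regeneration experiments —
run on different microarray/sequencing platforms and in different species —
share a common transcriptional signature. Absolute signal is not comparable
across platforms, so the unit of comparison is the within-experiment fold
change: for each probe set, the ratio of the high-regeneration group mean to
the low-regeneration group mean. On the log2 scale this is

$$\mathrm{log2fc}(p) = \log_2 \frac{\max(\bar{x}_{\mathrm{high}}, \varepsilon)}
{\max(\bar{x}_{\mathrm{low}}, \varepsilon)},$$

with a positive intensity floor $\varepsilon$ keeping the statistic finite
when a group mean is zero. Probes are collapsed to one value per gene
(median by default), genes are ranked within each experiment from largest to
smallest fold change (average ranks at ties), and each gene's ranks are
averaged across the $k$ experiments:

$$\bar r(g) = \frac{1}{k} \sum_{i=1}^{k} r_i(g).$$

All of this happens on the *common universe* $\mathcal{U}$ — the
intersection of the per-experiment gene sets after alias canonicalization
and mouse-to-human ortholog mapping — so every experiment ranks the
identical $U$ genes. Ranks are invariant under any strictly increasing
transform of one experiment's fold changes, which is precisely why ranking
is the right currency for cross-platform comparison: platform-specific
monotone distortions of intensity cancel out.

Top-$N$ signature lists are intersected across experiments. The central
overlap of $k$ independent uniformly drawn lists of sizes $n_i$ has
expectation $U \prod_i (n_i/U)$, and a seeded permutation test (draw each
list uniformly without replacement, $M$ times) gives
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(M+1)$ — the add-one convention
guarantees $p \in (0, 1]$. Term enrichment of the overlap uses the one-sided
Fisher's exact test: with $a$ list genes in a term of universe-restricted
size $m$ and a list of size $n$,
$p = P(X \ge a)$ for $X \sim \mathrm{Hypergeom}(U, m, n)$, adjusted across
terms by Benjamini–Hochberg and Bonferroni.

## Assumptions

* Each experiment has a well-defined high- versus low-regeneration
  contrast; which group is "high" must be declared (e.g. dsRNA-treated
  keratinocytes are the high-regeneration condition when that dataset is
  used as a positive control).
* Fold changes are meaningful at the gene level after probe collapse; the
  pipeline starts from expression tables or precomputed fold changes, not
  from raw CEL-level data (no RMA-style renormalization is attempted).
* Ortholog mapping is provided as a static table (HomoloGene/HCOP-style
  snapshot); no live database queries are made, so runs are reproducible
  against a pinned annotation version.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_top` | 200 | signature length per list; 100 is the natural choice for two-list designs with shallower data |
| `mode` | `per_dataset` | take top-N per experiment and intersect (what a k-way Venn of k lists requires); `aggregate` ranks by mean rank first, then cuts once |
| `collapse` | `median` | probe-to-gene collapse; robust to one discordant probe; `mean` and `max_abs` for sensitivity analysis |
| `floor` | data-driven | $\varepsilon$ = smallest positive intensity observed in the experiment, avoiding a per-platform magic constant |
| `n_perm` | 10000 | permutation count $M$; the p-value floor is $1/(M+1)$ |
| `adjustment` | `both` | report BH and Bonferroni columns |
| `seed` | 1 | drives the generator and the permutation null; recorded in every output's provenance |

Two genuinely open design choices were resolved as follows and are
switchable. First, ordering of operations: the aggregate statistic is
*rank-then-average* (each experiment is ranked, then ranks are averaged),
not average-the-fold-changes-then-rank; rank-then-average weights
experiments equally regardless of their fold-change scale, and the
alternative remains available as `mode = "aggregate"` vs per-dataset
top-N for the intersection question. Second, tie handling: ties within an
experiment get average ranks (preserving the rank-sum identity
$\sum r = U(U+1)/2$, which the tests assert on every table); an exact tie
at the top-N boundary is broken lexicographically by gene symbol —
deterministic, and recorded as a tie-break event in the signature's
provenance so an audit can see the cut was ambiguous.

One-to-many ortholog records are handled in exactly one place: mouse probes
are expanded onto each mapped human symbol, and the gene-level probe
collapse then produces a single value per human symbol. Human genes with no
mouse counterpart simply leave the universe at the intersection; nothing is
imputed. Symbol matching is case-sensitive — species casing (`Oas1a` vs
`OAS1`) is the ortholog map's job, never case folding.

The enrichment background is the common universe by default (pass a larger
gene set to `fisher_enrichment()` for a whole-array background); sidedness
is one-sided over-representation, the standard convention for term
enrichment, with `alternative = "two.sided"` available.

## What the synthetic generator emulates — and what it does not

`generate_study()` simulates $k$ probe-level experiments over a shared
universe of $U$ human-space genes: per-gene baseline log2 intensity
$\mathcal{N}(8, 1)$ (a typical microarray scale), a planted effect $\delta$
added to the high-regeneration group for $S$ signature genes (all probes of
a gene share its effect), i.i.d. $\mathcal{N}(0, \sigma)$ per-sample noise
on the log2 scale, uniform probe multiplicity in `probes_per_gene_range`,
and `samples_per_group` replicates per condition (default 3, a realistic
microarray design). Mouse-labelled experiments are written in mouse symbols
tied back to the human universe by the generated ortholog map; a fraction of
non-planted genes is left unmapped (so the realized common universe shrinks,
as with real annotation), a fraction of mapped genes gains a second mouse
paralog mapping to the same human symbol, and a fraction of non-planted
genes appears under an outdated alias that the generated alias table
corrects. Perturbations are restricted to non-planted genes so that the
planted signature is, by construction, measurable in every experiment. The
term database contains one term equal to the planted set plus 20 decoy
terms of size 10–50 drawn from non-planted genes.

The generator does **not** simulate array-specific normalization artifacts,
batch effects, correlated genes, or RNA-seq count distributions. Passing
tests therefore demonstrate that the pipeline's algebra and statistics are
correct and calibrated under an idealized noise model — not that any
particular biological dataset will yield a clean signature.

## Numerical choices and degenerate inputs

* Fold changes are always finite: the floor rule maps $(0, 4)$ with
  $\varepsilon = 1$ to $-2$, never $-\infty$.
* `n_top = 0` is allowed and produces empty signatures and overlap with a
  warning; `n_top > U` truncates to the full universe.
* A single experiment ($k = 1$) degenerates cleanly: the aggregate equals
  the experiment's own ordering and the central overlap is the list itself
  with permutation $p = 1$.
* An empty signature reports precision as `NA` (undefined) and recall 0;
  a study with no planted genes reports recall `NA`.
* Terms with no member in the universe are skipped and logged, not scored.
* All randomness (generator, permutation null) is seed-scoped with
  `withr::with_seed`, so identical configs give byte-identical outputs
  without disturbing the caller's RNG.

## Verification problem sizes

The shipped checks run at desk scale, chosen so the whole suite completes
in about a minute: exact agreement of the six-gene worked aggregation
example; Fisher p-values against an explicit choose()-sum enumeration over
all 2×2 tables with margins ≤ 12 (5,460 tables); the permutation null
against full enumeration of every possible draw on universes of up to 8
genes at $M = 50{,}000$; null calibration of the mean three-way top-200
overlap over 200 simulated null studies at $U = 5000$ (run with one probe
per gene and two samples per group — the smallest valid design, since the
null property does not depend on either); and planted-signature recovery at
$U = 2000$, $k = 3$, $S = 20$, $\delta = 3\sigma$, $N = 200$.

## Known limitations

* Venn region bookkeeping is implemented for $k \le 3$ lists (the designs
  this method targets); for larger $k$ the pipeline still reports the
  central intersection.
* The permutation null models lists drawn independently and uniformly; if
  real rankings are correlated between experiments for technical reasons
  (shared subjects, shared platform), the null is anti-conservative.
* Rank aggregation uses the unweighted mean; no experiment-reliability
  weighting is attempted.
* The enrichment engine takes any GMT file but ships no ontology; term
  databases (GO, DAVID, PANTHER exports) are the user's input, and no
  parent/child term propagation is performed.
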