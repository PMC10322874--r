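---
title: "Glycan niche metrics from metagenomic CAZyme profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycan niche metrics from metagenomic CAZyme profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyconiche)
```

## The model

A microbial taxon's capacity to degrade polymeric carbohydrates is encoded
in its repertoire of carbohydrate-active enzymes (CAZymes). Treating each
degradative CAZyme family as a "resource dimension", a taxon's **glycan
niche** in a sample is the distribution of its CAZyme gene abundance over
families: a taxon concentrating its abundance in a handful of families is a
substrate specialist; one spreading it over many families is a generalist,
and two taxa with similar distributions compete for similar substrates.

The analysis path is:

1. **Abundance normalization.** Each gene's abundance is
   RPKM = 1e6 × (reads mapped / gene length in kb) / library size,
   removing gene-length and sequencing-depth effects (`rpkm()`).
2. **Profile construction** (`build_profile_matrix()`). Per sample, genes
   are aggregated into a taxon × family RPKM matrix at a chosen rank.
   Glycosyltransferases (GT) are excluded by default — they build rather
   than break glycosidic bonds, so the niche is defined over the
   degradative classes GH, PL, CE, AA and CBM. Genes on contigs of ≤ 500 bp
   are dropped (assembly fragments too short for reliable annotation);
   the filter is strict, so a 501 bp contig passes.
3. **Niche metrics** (`levins_B()`, `levins_standardized()`,
   `shannon_evenness()`, `morisita_horn()`, `overlap_matrix()`,
   `niche_width_table()`). With p_ij the proportion of family j in taxon
   i's degradative CAZyme abundance:
   B = 1/Σp², B_A = (B−1)/(n−1), B_i = −Σ p ln p, and
   O_ik = 2Σ p_i p_k / (Σp_i² + Σp_k²).
4. **Group statistics** (`family_screen()`, `bray_curtis()`, `pcoa()`,
   `permanova()`): per-family Wilcoxon rank-sum screens between two sample
   groups with Benjamini–Hochberg control, and community-level ordination
   and permutation tests on Bray–Curtis distances.
5. **Transporter strategies** (`classify_transporters()`,
   `strategy_score()`): carbohydrate-transporter KOs aggregated into ABC,
   PTS, MFS, TonB and SusC classes, scored against the
   sharer/scavenger/selfish uptake typology.

### Assumptions

* Annotation is taken at face value: one pre-reconciled CAZyme family set
  per gene and one KO per transporter gene. No re-annotation is attempted.
* Read counts are proportional to gene (and organism) abundance; RPKM is
  an adequate within-sample normalization. Compositional effects between
  samples are handled only through the rank-based and permutation-based
  tests, not by an explicit compositional model.
* A multi-domain gene (e.g. GH13;CBM48) is counted at full RPKM in every
  family it carries, mirroring family-level tallies from domain
  annotations. This means family columns are not strictly additive
  partitions of genes; an equal-split mode (`multi_domain = "split"`) is
  provided for analyses that need additivity.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `exclude_classes` | `"GT"` | niche over degradative classes only |
| `contig_min_bp` | 500 (strict >) | short-contig annotation reliability |
| `rank` | phylum/class/genus | aggregation level of the niche |
| `n` in `levins_standardized` | dataset-wide family count | see below |
| `top_fraction` (LCA) | 0.1 | conventional DIAMOND-style top-percent window |
| `n_permutations` | 999 | conventional permutation count; p ≥ 1/1000 |
| BH level | 0.05 | defensible default for family screens |
| sharer secretion threshold | 0.25 | see strategy rule below |

**Standardization denominator.** B_A scales B against the total number of
degradative families predicted in the dataset, so taxa in the same dataset
share one scale and B_A is comparable across taxa. Standardizing against
each taxon's own family count is also defensible (it measures evenness
within the realized repertoire rather than breadth against the community's)
— `niche_width_table(m, n = ...)` accepts either; the dataset-wide count is
the default because breadth against the community repertoire is the
ecologically interesting quantity.

**RPKM denominator.** The library size is taken from the sample metadata
(`total_reads`, the post-QC read total) rather than the mapped-read total.
The two differ by the unmapped fraction; since the denominator is supplied
by the user per sample, either convention can be used by filling
`total_reads` accordingly.

**LCA window.** Hits within 10% of the best score form the consensus; ties
at the boundary are retained (≥). The window is exposed because database
and scoring choices upstream shift what a sensible window is.

**Strategy rule.** The sharer/scavenger/selfish typology is qualitative in
origin. The package operationalizes it transparently: with transporter
fractions f_ABC, f_specific = (PTS + MFS + TonB) and f_SusC, the label is
*scavenger* if f_ABC is strictly greatest (broad uptake of dissolved
hydrolysis products), *selfish* if f_SusC is strictly greatest
(periplasmic capture minimizing diffusive loss), *sharer* if f_specific is
strictly greatest **and** at least 25% of the taxon's CAZyme abundance is
secreted (external hydrolysis feeding the commons), and *mixed* otherwise,
including exact ties. The rule and threshold are echoed in every result so
downstream users see exactly what was applied. It is a heuristic
classification aid, not a measured phenotype.

## The synthetic-data generator

`sim_config()`/`simulate_community()` generate gene tables with known
ground truth so that every stage can be validated without sequencing data.

* Each taxon's niche proportions p are drawn from a symmetric Dirichlet
  over its family set; the concentration α tunes evenness (α → 0
  specialist, α → ∞ generalist; default α = 1, a flat prior giving a broad
  mix of widths).
* Pairwise overlap is planted by mixing a shared uniform component into
  both members of a pair: p ← (1−s)·private + s·shared. The exact
  Morisita–Horn value of the *realized* vectors — computed by
  `truth_metrics()`, an independent straight-loop implementation — is
  recorded as truth, not the nominal s.
* Defaults describe a small estuarine-like setting: 5 taxa × 40
  degradative families, plus 10 GT families carrying 30% of read mass
  (GTs being the most abundant class in such data) to exercise the GT
  filter; the five condition groups (surface/bottom × free-living/particle
  plus sediment) with two samples each; 1e5 reads per sample. A library of
  1e5 reads keeps the simulation fast while leaving multinomial noise on
  family proportions around the 1e-2 scale, small enough for the recovery
  checks below to be meaningful.
* Genes: each non-zero family gets at least one gene; family mass is split
  equally among its genes; lengths are log-normal (median 1 kb), truncated
  to [500, 5000] bp. Expected read counts are proportional to mass × gene
  length, so RPKM is an unbiased estimate of the planted proportions.
  Reads are multinomial per sample (a Dirichlet-multinomial overdispersion
  switch exists for robustness checks). Group effects multiply chosen
  family weights in chosen groups before renormalization.
* Transporter genes follow a three-strategy KO spectrum (ABC-dominant,
  SusC/TonB-dominant, mixed specific) on the first three taxa, at 5% of
  read mass.

**What the generator does not emulate:** assembly and mapping artifacts
(chimeras, multi-mapping, coverage bias), real phylogenetic correlation
between taxa, compositional coupling between samples beyond the fixed
library size, and annotation error. Passing recovery tests therefore shows
that the estimators are consistent for the generating model — not that
real annotation pipelines are unbiased.

## Numerical choices

* Proportion vectors are accepted when |Σp − 1| ≤ 1e-6 and renormalized
  internally; 0·ln 0 is defined as 0 in the Shannon index.
* Overlap matrices keep the mathematical diagonal of 1; the conventional
  lower-triangular display with a "0.00" diagonal is a writer option
  (`write_matrix(..., layout = "table1_style")`), not a data value.
* The rank-sum test is exact (enumeration distribution) for combined
  sample sizes ≤ 12 without ties, and otherwise uses the normal
  approximation with tie-corrected variance and continuity correction.
* PERMANOVA p-values use the (1 + exceedances)/(1 + permutations)
  correction; with 999 permutations the smallest attainable p is 1/1000.
  Permutations are sampled randomly, so in tiny designs the original
  partition can recur among them — the test is valid, but the minimal p is
  reached reliably only when the number of distinct partitions is large.
* PCoA drops axes with negative eigenvalues (reporting the full spectrum);
  Bray–Curtis distances are not Euclidean in general, so small negative
  eigenvalues are expected and harmless.
* Unclassified genes at the aggregation rank go to an
  `unclassified_<rank>` bucket; unmapped families to an `unmapped`
  substrate column; unmapped transporter KOs to an explicit report — no
  row or abundance is ever dropped silently.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate at sizes chosen to make
the checks sharp yet quick: 1,000 random proportion vectors against
brute-force oracles (tolerance 1e-10); 100 seeded simulation replicates
for parameter recovery (|Ô − O| ≤ 0.02, |B̂_A − B_A| ≤ 0.05 required in ≥
95%); exhaustive rank-sum enumeration for all tie-free patterns up to
n + m = 10; 200 label-shuffled null datasets for PERMANOVA calibration at
α = 0.05; and a 6 + 6 sample planted-effect run with five 4-fold
differential families for the end-to-end screen.

## Known limitations

* RPKM-based proportions are compositional; strong blooms of one family
  depress all others' proportions. Niche *width* is robust to this (it is
  computed within taxon), but cross-sample family comparisons inherit the
  usual compositional caveats.
* The Morisita–Horn index is abundance-weighted; rare-family overlap
  contributes little, so high overlap statements are dominated by each
  pair's abundant families.
* The strategy rule collapses a continuum into four labels; taxa near ties
  flip labels under small abundance perturbations and are reported as
  "mixed" only at exact ties.
* The LCA step assumes hit scores are comparable across hits of one gene;
  cross-database score mixtures need user care.
* Sulfatases and other non-CAZyme degradative markers are carried only as
  ordinary annotation columns, not modeled.
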