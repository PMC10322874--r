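# glyconiche

Glycan-niche analysis of metagenomic CAZyme (carbohydrate-active enzyme)
annotations.

Shotgun metagenomes of aquatic and sediment microbial communities are
routinely annotated for CAZyme families (GH, PL, CE, AA, CBM, GT) and
carbohydrate transporters. `glyconiche` turns such flattened gene-annotation
tables into ecological statements about **glycan niches**: which
polysaccharide substrates a taxon can attack, how wide its enzymatic
repertoire is, and how strongly it overlaps with other taxa. It is written
for microbial ecologists who have per-ORF annotation tables (from e.g.
dbCAN, Kofam, SignalP upstream) and want a reproducible, tested path from
counts to niche metrics and group statistics.

## What it computes

For each taxon *i* in a sample, the abundance of CAZyme family *j* is the
summed RPKM of its genes,

    RPKM = 1e6 * (reads mapped / gene length in kb) / library size,

restricted to degradative classes (GT excluded) and contigs > 500 bp. With
p_ij the proportion of family *j* in taxon *i*'s total degradative CAZyme
abundance N_i:

* **Levins niche width** `B = 1 / Σ_j p_ij²` (inverse Simpson
  concentration), and its standardization `B_A = (B − 1)/(n − 1)` to [0, 1]
  against the dataset-wide family count *n*;
* **Shannon–Wiener evenness** `B_i = −Σ_j p_ij ln p_ij`;
* **Morisita–Horn overlap** between taxa *i* and *k*,
  `O_ik = 2 Σ_j p_ij p_kj / (Σ_j p_ij² + Σ_j p_kj²)` — 1 for identical
  profiles, 0 for disjoint ones.

Around this core: lowest-common-ancestor lineage assignment from scored
hits, substrate-category aggregation (α/β-glucans, N-glycans,
cellulose/hemicellulose, β-mannosides, lignin, sulfated fucose/rhamnose
polysaccharides, pectin, alginate), transporter-class profiling
(ABC/PTS/MFS/TonB/SusC) with sharer/scavenger/selfish strategy labels, and
group comparisons (per-family Wilcoxon rank-sum screen with
Benjamini–Hochberg control, Bray–Curtis, PCoA, PERMANOVA with 999
permutations). A seeded community simulator with closed-form truth metrics
makes every stage testable without sequencing data.

## Worked example

```r
library(glyconiche)

# simulate a small estuarine-like community with a planted overlap pair
sim <- simulate_community(sim_config(seed = 1))

# taxon x family profile for one sample (GT excluded, contigs > 500 bp)
m <- build_profile_matrix(sim$genes, sim$meta, "SF_1", rank = "phylum")

niche_width_table(m)[1:3, ]
#>         taxon n_families        B       B_A      B_i
#> 1 SimPhylum01         40 35.10478 0.8744816 3.627627
#> 2 SimPhylum02         40 35.65493 0.8885881 3.631871
#> 3 SimPhylum03         40 16.70935 0.4028040 3.130020

round(overlap_matrix(m)[1:3, 1:3], 3)
#>             SimPhylum01 SimPhylum02 SimPhylum03
#> SimPhylum01       1.000       0.919       0.590
#> SimPhylum02       0.919       1.000       0.583
#> SimPhylum03       0.590       0.583       1.000
```

Taxa 1 and 2 were simulated with 60% shared niche mass; their planted
exact overlap is 0.920 and the estimate from 1e5 sampled reads is 0.919.
`B_A` near 1 marks generalists spreading abundance evenly over the 40
families; `B_i` is the corresponding Shannon evenness (ln 40 ≈ 3.69 at
uniformity).

The full pipeline (profiles → niche metrics → overlap → substrates →
transporters → ordination/PERMANOVA, plus a checksummed run manifest):

```r
res <- run_pipeline(sim$genes, sim$meta, "results/", rank = "phylum", seed = 99)
res$compare$permanova
#> PERMANOVA: pseudo-F = 1.610, R2 = 0.315, p = 0.01 (999 permutations, seed 99)
```

A thin command-line front end is in `inst/scripts/glyconiche.R`
(`validate`, `simulate`, `run` subcommands).

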