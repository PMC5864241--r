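# assemblyproc

Phylogenetic null-model inference of the ecological processes that assemble
microbial communities along environmental gradients — written for microbial
ecologists who have an OTU table, a phylogeny of the OTUs and per-sample
metadata (soil pH, successional age, coordinates) and want to know *how
much* of the compositional turnover between their samples is governed by
deterministic selection versus stochastic dispersal and drift.

## The statistics at its core

For a community `k` with taxon relative abundances `f` and patristic
distances `d` between taxa:

* **MNTD** and its standardized effect size
  `SES.MNTD = (MNTD_obs − mean(MNTD_null)) / sd(MNTD_null)`, the null being
  999 permutations of the taxon labels on the distance matrix. Negative
  values mean co-occurring taxa are more closely related than chance
  (phylogenetic clustering).
* **βMNTD** between samples `k` and `m`:
  `βMNTD = ½ [ Σ_{i∈k} f_ik · min_{j∈m} d(i,j) + Σ_{j∈m} f_jm · min_{i∈k} d(j,i) ]`
  (abundance-weighted; shared taxa self-match at distance zero), and its
  z-score **βNTI** against the same null.
* **RC_bray**: the rank of the observed Bray–Curtis dissimilarity within a
  null that re-assembles both communities from the dataset-wide pool
  (richness and depth preserved; taxa drawn by occupancy, reads by
  dataset-wide relative abundance), rescaled to [−1, +1].

Each sample pair is then classified:

| βNTI | RC_bray | process |
|---|---|---|
| > +2 | — | variable selection |
| < −2 | — | homogeneous selection |
| within ±2 | > +0.95 | dispersal limitation |
| within ±2 | < −0.95 | homogenizing dispersal |
| within ±2 | within ±0.95 | undominated |

and the relative contribution of each process is the percentage of pairs in
its class, overall and within successional-age or pH categories. The
package also estimates per-OTU pH niche optima (abundance-weighted means
and Huisman–Olff–Fresco response curves), tests their phylogenetic signal
with Mantel correlograms, and relates βNTI to pH and spatial distance with
Mantel and partial Mantel tests — the prerequisite checks for reading
phylogenetic turnover ecologically. A synthetic community generator with
known assembly regimes validates the whole chain end to end.

## Worked example

Simulate a 25-sample, 80-taxon dataset assembled under homogeneous
selection (every sample at the same extreme pH, selection confined to one
acid-specialist clade), then run the full analysis:

```r
library(assemblyproc)

b <- scenario("homogeneous_selection", seed = 1)
fit <- assembly_process(b$table, b$tree, b$meta, n_iter = 999, seed = 1)
fit
#> Community assembly process inference
#>   80 taxa x 25 samples, rarefied to 1000 reads, 999 null iterations
#>   mean SES.MNTD: -3.511
#>   process fractions (%):
#>     variable_selection          0.0
#>     homogeneous_selection      88.8
#>     dispersal_limitation        0.0
#>     homogenizing_dispersal      1.4
#>     undominated                 9.9

head(fit$pairs[, c("sample_i", "sample_j", "bmntd", "bnti", "rc_bray", "process")], 4)
#>   sample_i sample_j      bmntd      bnti    rc_bray               process
#> 1       S1       S2 0.05534377 -3.745981  0.7177177 homogeneous_selection
#> 2       S1       S3 0.04312689 -2.834752 -0.7087087 homogeneous_selection
#> 3       S1       S4 0.09592177 -3.301786  0.3023023 homogeneous_selection
#> 4       S1       S5 0.03840501 -3.762191  0.3493493 homogeneous_selection
```

Read: communities are strongly phylogenetically clustered (mean
SES.MNTD = −3.5) and 88.8% of pairwise comparisons show significantly
*less* phylogenetic turnover than the null expects (βNTI < −2) — the
fingerprint of a constant, stringent environmental filter, which is exactly
how this dataset was generated. `summary(fit)` adds the per-category
partitions and Mantel tests; `plot(fit)` draws βNTI against ΔpH or the
process fractions.

With real data, replace the simulated bundle:

```r
table <- read_community_table("otu_table.tsv")
tree  <- ape::read.tree("otus.nwk")
meta  <- read_sample_metadata("metadata.tsv")   # sample_id, pH, age, lat, lon
fit <- assembly_process(table, tree, meta, depth = 4854, n_iter = 999, seed = 42)
```

`run_assembly()` wraps the same fit and writes `ses_mntd.tsv`,
`bnti_pairs.tsv`, `process_fractions.tsv`, `correlogram.tsv`,
`mantel_tests.tsv` and a run log to an output directory;
`run_sensitivity()` repeats the analysis across rarefaction depths and
reports cross-depth concordance. A thin command-line wrapper lives in
`inst/scripts/assemblyproc.R`.

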