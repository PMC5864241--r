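---
title: "Phylogenetic null models for community assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic null models for community assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblyproc)
```

## The inference problem

Soil bacterial communities are assembled by a mixture of deterministic
processes (environmental selection, here chiefly by soil pH) and stochastic
ones (dispersal and drift). Neither is observable directly from a snapshot
OTU table, but they leave different fingerprints in *phylogenetic* turnover
when ecological niches are phylogenetically conserved: selection toward a
common environment pulls co-occurring taxa into the same clades, selection
toward different environments pushes communities into different clades, and
dispersal processes reshuffle composition without regard to phylogeny.

`assemblyproc` implements the null-model framework that turns this logic
into per-sample and per-pair statistics:

* **SES.MNTD** — the z-score of a community's mean nearest taxon distance
  (MNTD) against a null in which the taxon labels of the patristic distance
  matrix are permuted (`taxa.labels` scheme, 999 permutations by default).
  SES.MNTD < 0 indicates phylogenetic clustering, > 0 overdispersion.
* **βMNTD / βNTI** — abundance-weighted between-community MNTD, and its
  z-score against the same label-permutation null. βNTI < −2 is read as
  *homogeneous selection*, βNTI > +2 as *variable selection*.
* **RC~bray~** — for pairs whose phylogenetic turnover is within the null
  expectation (|βNTI| ≤ 2), a Raup–Crick null on Bray–Curtis dissimilarity
  discriminates the stochastic explanations: each community is re-assembled
  probabilistically from the dataset-wide pool, preserving its richness and
  read depth, drawing taxa with probability proportional to occupancy and
  reads proportional to dataset-wide relative abundance (each drawn taxon is
  seeded with one read; the remaining reads are multinomial). The rank of
  the observed dissimilarity, with half weight on ties, is rescaled to
  [−1, +1]. RC > +0.95 indicates *dispersal limitation*, RC < −0.95
  *homogenizing dispersal*, |RC| ≤ 0.95 the *undominated* fraction.

The five classes tile the (βNTI, RC) plane. The published thresholds use
strict inequalities, which leaves the measure-zero boundaries ±2 and ±0.95
unassigned; we place |βNTI| = 2 on the stochastic branch and |RC| = 0.95 on
undominated so that classification is total. Undefined statistics (a null
standard deviation of zero, fewer than two taxa in a sample, missing RC
where it is needed) propagate as `NA`/`unclassifiable`, never silently as
zeros.

A prerequisite of the whole approach is *phylogenetic signal* in the niche:
closely related taxa must prefer similar pH. The package estimates per-OTU
pH optima two ways — the relative-abundance-weighted mean pH of the samples
an OTU occupies, and Huisman–Olff–Fresco (HOF) response curves — and tests
signal with a Mantel correlogram between niche-optimum differences and
patristic distances.

## Null-model mechanics and numerical choices

**One label permutation per iteration, shared by all samples and pairs.**
Each null iteration permutes the taxon labels of the cophenetic matrix once
and recomputes MNTD for every sample (or βMNTD for every pair). This is the
behaviour of the `taxa.labels` null and makes a 999-iteration run
O(iterations × pairs). Whether the original analyses used shared or
per-pair permutations is not documented; shared is our default.

**Weighting defaults.** βMNTD is abundance-weighted (the convention the
framework prescribes); SES.MNTD is unweighted by default, matching the
default of the reference implementation, with a flag for either choice.
Unweighted βMNTD pools the nearest-taxon distances from both directions
into a single mean (the `comdistnt` convention) rather than averaging the
two directional means; the two differ when richness is unequal.

**Shared taxa self-match.** In βMNTD a taxon present in both communities
finds itself across the pair at distance zero, in the observed statistic
*and* in every null draw (label permutation fixes the zero diagonal).
Compositionally identical communities therefore have βMNTD ≈ 0 with almost
no null variance — βNTI is a statement about the taxa that *differ* between
two samples, a point that matters for simulation design (below).

**RC~bray~ ties.** Bray–Curtis values are compared with a tolerance of
1e−12; exact ties receive half weight, the standard Raup–Crick
discretization. RC is computed for every pair (cheap at package scale); the
|βNTI| < 2 restriction is applied at classification, keeping the full
matrix available for diagnostics.

**Mantel machinery.** The Mantel statistic is the Pearson (optionally
Spearman) correlation of the unfolded lower triangles; significance comes
from simultaneous row/column permutations of the first matrix, two-tailed
by default since the sign of a turnover–environment association is not
fixed a priori. The partial Mantel statistic is the standard first-order
partial correlation
r~AB·C~ = (r~AB~ − r~AC~ r~BC~) / √((1 − r~AC~²)(1 − r~BC~²)),
with A's labels permuted. A control matrix collinear with A raises an
error; a control identical to B returns 0, the residual limit. The
correlogram cuts patristic distances into equal-width classes (Sturges'
rule on the pair count by default), computes per class a Mantel statistic
against the class-membership indicator with the sign flipped so that
positive r means "more similar niches than average at this distance", and
permutes the niche matrix's labels. Multiple testing uses plain Bonferroni
by default — the correction named in the procedure this package
re-implements — with progressive Bonferroni (class k corrected by factor k)
available by flag; plain Bonferroni also keeps the family-wise error of the
negative control (no signal for i.i.d. optima) at the nominal 5%.

**HOF fitting.** All seven response types are fitted by binomial maximum
likelihood on read counts with the pH axis rescaled to [0, 1]: I flat, II
monotone logistic, III monotone with a free plateau, IV symmetric unimodal,
V skewed unimodal, VI bimodal with equal maxima, VII bimodal with unequal
maxima (1 to 5 parameters). Optimization is Nelder–Mead from several
data-informed starts plus warm starts from the best fit of each nested
simpler type, polished by BFGS. Model choice is AICc with two
stabilizations: the simplest model within 2 AICc units of the optimum wins,
and a selected bimodal type whose fitted curve has no genuine second mode
(secondary peak < 15% of the primary, or no pronounced trough) is demoted
to the best of I–V. At read depths of ~1000 the binomial likelihood is
sharp enough that raw AICc otherwise rewards the richest types for fitting
tail noise. Optional bootstrap stabilization (`n_boot`) refits on resamples
and takes the modal choice. Type I has no optimum and is excluded; monotone
optima sit at the edge of the observed range and are flagged. OTUs in fewer
than 5 samples are not fitted.

**Reproducibility.** Every stochastic routine takes a `seed`, evaluates
under it without disturbing the caller's RNG stream, and one master seed
spawns derived per-stage streams in `assembly_process()`. Identical inputs,
iteration counts and seeds give bit-identical output, including the TSV
files written by `run_assembly()`.

## Data preparation contracts

Dataset-wide singletons (total count exactly 1) are removed first — such
OTUs are disproportionately sequencing errors and phylogenetic null models
are sensitive to them. Rarefaction subsamples each sample without
replacement (hypergeometric) to a common depth, dropping samples below it;
the default depth is the smallest sample sum. Table and tree are reconciled
by pruning the tree to the table's taxa and dropping (with a warning) taxa
absent from the tree, because MNTD-family metrics need complete distance
coverage. Spatial distance is the haversine great circle (sphere radius
6,371 km); the source procedure does not name its spatial metric, so the
choice is documented here and isolated in one function.

## What the synthetic generator emulates

The generator exists so the full pipeline can be exercised, and its
inferences validated, with no external data: it produces a Yule phylogeny
(rescaled to unit height; tips `OTU_1…n`), per-tip pH optima, sample
metadata (pH, successional age, coordinates on a short transect), and
multinomial read counts at fixed depth — by default 80 taxa, 25 samples and
1,000 reads per sample, the sizes used throughout the validation suite
(chosen so a 999-iteration analysis of every preset completes in minutes on
one core).

Trait evolution is Brownian motion from a root optimum of 6.5 with rate
σ² = 2.25 pH² per unit tree height (tip sd 1.5, spanning roughly pH 3–9,
the range of real soil surveys), clipped to [3, 9]. For the selection
presets a *clade-radiation* variant concentrates divergence on deep
branches: Brownian motion runs only until the tree has n lineages, each
lineage's descendants inherit its value plus small twig noise
(sd 0.1 pH), and the clade niche centres are spread along the pH axis in
the order of the Brownian draw. This is the strong form of clade-level
niche conservatism (deeply conserved pH preference of major soil lineages)
that the selection regimes presume.

Sampling weight of taxon i in sample s is
m~i~ · exp(−½ (|pH~s~ − o~i~| / τ)^shape^), with lognormal base abundances
m~i~, selection breadth τ (∞ = neutral) and a generalized-Gaussian shape
exponent (2 = Gaussian default; the presets use a hard tolerance window,
shape = ∞, because at an 80-taxon pool the Gaussian tail admits enough
out-of-guild stragglers to blur the phylogenetic signature). A per-site
Bernoulli colonization lottery (`p_colonize`) makes each site realize a
different subset of the taxa selection would admit. This membership
turnover is essential: βNTI is blind to shared taxa, so communities that
are *identical* under strong selection carry no homogeneous-selection
signal — the detectable signature is *different members of the same clade*
at every site.

The six presets of `scenario()`:

* `homogeneous_selection` — all samples at the niche centre of one
  phylogenetically tight specialist clade (~20% of the pool, chosen for
  size, niche isolation and internal tightness), hard window τ = 0.35,
  colonization 0.65.
* `variable_selection` — samples alternate between the niche centres of
  the two most niche-separated adequate clades; cross-extreme pairs carry
  the variable-selection signature.
* `dispersal_limitation` — no selection; each sample draws from a local
  pool of taxa whose home positions lie within 0.12 of the site on a unit
  transect. Pools are wide enough that the Raup–Crick null's membership
  draws are rarely disjoint — otherwise ties at Bray–Curtis = 1 cap RC
  below +0.95 and the signature disappears.
* `homogenizing_dispersal` — no selection; all samples copy 90% of their
  reads from one shared realized metacommunity profile (plus a multinomial
  remainder and a few sample-specific rare taxa that keep the pool larger
  than any one sample), so observed dissimilarity falls far below the
  null.
* `neutral` — independent multinomial draws from the metacommunity.
* `undominated` — weak selection (τ = 3, Gaussian) along a pH 4–9
  gradient; no single process dominates.

What the generator does **not** emulate: sequencing error and chimeras
(the singleton filter is exercised only trivially), compositional biases
of PCR and primer choice, overdispersion beyond multinomial sampling,
non-equilibrium dynamics through time, and trees with topology or
branch-length error. Recovery of the generating regime by the pipeline
therefore shows internal consistency of the inference chain under its own
assumptions — it does not validate those assumptions on real sequencing
data, where signal strength, pool sizes and richness are all different
(typically thousands of taxa, where the statistics are far better
powered than at desk scale).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_iter` | 999 | iterations | the customary permutation count; p-value floor 1/1000 |
| rarefaction `depth` | min sample sum | reads | equalizes sampling effort |
| βNTI thresholds | ±2 | z | ~2 sd of the null |
| RC thresholds | ±0.95 | — | the published Raup–Crick cutoff |
| `tau` | ∞ (off) | pH | selection breadth of the generator |
| `sigma2` | 2.25 | pH²/height | tip spread matching real soil pH ranges |
| pH bins | width 0.5 | pH | the partitions' category width; overridable |
| age bins | distinct ages | years | chronosequence stages are discrete |
| HOF `min_occ` | 5 | samples | below this the seven-type fit is meaningless |
| `n_boot` | 0 (off) | resamples | bootstrap model-choice stabilization |

## Known limitations

* The taxa-label null is the only randomization scheme; frequency- and
  richness-preserving swap algorithms are out of scope.
* βNTI loses power at small taxon pools: with ~80 taxa its magnitude is
  bounded by the handful of non-shared taxa contributing independent
  nearest-neighbour terms, which is why the generator's selection presets
  need coherent clades and membership turnover to be recoverable at all.
* HOF type II has no free maximum scale (pure logistic), so monotone
  responses that saturate below 1 select type III; both are monotone and
  are treated alike downstream.
* The GAMM of SES.MNTD against pH and age is intentionally not fitted
  here; `assembly_process()` returns the tidy per-sample table
  (`ses_mntd`) that such a model consumes.
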