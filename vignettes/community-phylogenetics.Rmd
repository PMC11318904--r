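---
title: "Community phylogenetic structure along elevational gradients with phylograd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community phylogenetic structure along elevational gradients with phylograd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylograd)
```

## The scientific problem

Ecological communities are assembled from a regional species pool by
processes that leave a phylogenetic signature. Environmental filtering
selects for shared (usually phylogenetically conserved) tolerances and
packs a community with close relatives; competitive exclusion of similar
species spaces co-occurring taxa out across the phylogeny. Elevational
gradients compress large environmental change into short distances and are
the classic natural experiment for these ideas: a tropical mountain
transect can run from lowland rainforest to the timberline within a few
tens of kilometres, and insect communities sampled along it — such as the
geometrid moth assemblages of Mt. Wilhelm, Papua New Guinea, whose
published site table ships with this package — let us ask whether high
elevations hold clustered, filtered subsets of the lowland fauna.

phylograd implements the complete analysis chain for such a study: alpha
phylogenetic structure with null-model standardization, phylogenetic beta
diversity decomposed into turnover and nestedness, clustering of
communities by inter-community phylogenetic distance, and multimodel
inference over site-level environmental predictors. Every statistic is
computed from two objects: a rooted, branch-length-bearing phylogeny of the
species pool (`ape::phylo`) and a binary sites × species tibble ordered by
elevation.

## Alpha structure: MPD, MNTD, Faith's PD and their effect sizes

For a community \(S\) with cophenetic (path-length) distances \(d(i,j)\):

* **MPD** — mean of \(d(i,j)\) over all unordered pairs in \(S\): deep,
  tree-wide relatedness.
* **MNTD** — mean over \(i \in S\) of \(\min_{j \ne i} d(i,j)\): terminal,
  tip-level relatedness.
* **Faith's PD** — total branch length of the subtree spanning \(S\). By
  default the path connecting the subtree to the root is included
  (`include_root = TRUE`, matching the reference convention); the flag is
  exposed because the literature is split, and it propagates consistently
  into the shared-branch accounting of PhyloSor so that the component
  identity \(a + b = \mathrm{PD}_1\) always holds.

Raw metrics depend on richness, so each is standardized against a
taxon-label-shuffling null: each iteration draws one uniform permutation of
the tip labels of the *full pool present in the tree* and recomputes the
metric for every site from that same permutation. Site rows are untouched,
so richness is preserved by construction. With null mean \(\mu\) and sample
standard deviation \(\sigma\) (denominator \(n-1\), matching the reference
implementation),

\[ \mathrm{NRI} = -\frac{\mathrm{MPD}_{obs} - \mu}{\sigma}, \qquad
   \mathrm{NTI} = -\frac{\mathrm{MNTD}_{obs} - \mu}{\sigma}, \qquad
   \mathrm{SES.PD} = \frac{\mathrm{PD}_{obs} - \mu}{\sigma}. \]

The sign flip makes positive NRI/NTI mean *clustering*; SES.PD keeps its
natural sign, so depauperate phylogenetic diversity is negative. Indices
beyond ±1.96 — the two-sided 5% normal demarcation — are flagged
significant. The default is 999 Monte-Carlo iterations; on small pools an
exact mode enumerates every distinct taxon subset of the observed richness
instead (`mode = "exhaustive"`; the worked 4-tip example in
`?ses_indices` gives NRI = +1.29099 exactly).

Degenerate cases are explicit: sites with fewer than two taxa have
undefined MPD/MNTD (NRI/NTI are `NA`) but a valid SES.PD; a null ensemble
with zero spread yields `NA`, never ±Inf. Near-zero null variance is
detected relative to the accumulation round-off (a variance below
\(10^{-14}\max(\mu^2, 1)\) is treated as exactly zero), so a full-pool
community — which label shuffling cannot change — reports a zero-sd
ensemble rather than a numerically tiny one.

## Beta structure: PhyloSor, its decomposition, COMDIST

For two communities, let \(a\) be the branch length lying in both spanning
subtrees and \(b, c\) the lengths unique to each. Total dissimilarity,
true-turnover and nestedness-resultant components are

\[ \beta_{sor} = \frac{b + c}{2a + b + c}, \qquad
   \beta_{sim} = \frac{\min(b, c)}{a + \min(b, c)}, \qquad
   \beta_{sne} = \beta_{sor} - \beta_{sim}, \]

the Baselga decomposition applied to branch lengths; replacing lengths with
species counts gives the species-level Sorensen variant, and on a unit-star
phylogeny the two coincide (a property test). The identity
\(\beta_{sor} = \beta_{sim} + \beta_{sne}\) holds exactly by construction
and is asserted to \(10^{-12}\) across thousands of random pairs. COMDIST
is the unweighted mean cophenetic distance over all cross-community pairs
(shared species contribute zero-distance self-pairs); the site × site
COMDIST matrix feeds standard agglomerative clustering. Average linkage
(UPGMA) is the default — no particular linkage is canonical for community
dendrograms — and heights are reported as raw merge distances (the
`stats::hclust` convention, *not* halved), stated here because only the
topology is usually compared across studies. Agglomeration ties are broken
deterministically by `hclust`'s ordering.

## Predictor models

Site predictors are standardized to z-scores (sample sd). The candidate set
for each response is all \(2^p\) additive subsets of the predictors — with
the three predictors of the shipped site table, 8 models from the
intercept-only null to the full model; no interactions. Fits are ordinary
least squares with the Gaussian *maximum-likelihood* log-likelihood
\(-\tfrac{n}{2}(\log 2\pi + \log(\mathrm{RSS}/n) + 1)\) (residual variance
divided by \(n\)), and the parameter count \(k\) includes the residual
variance. This pair of conventions is what makes small-sample AICc,

\[ \mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n - k - 1}, \]

reproduce the published model-selection table for the shipped data to
printed precision (`rank_models(mt_wilhelm_sites(), "nri", ...)`); REML or
an unbiased-variance likelihood does not. Akaike weights are
\(w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}\). Quadratic responses are
fitted on an orthogonalized polynomial basis for conditioning; the reported
quadratic-term p-value is basis-invariant (asserted against the raw-basis
fit), and an exactly interpolating fit is flagged rather than given a
meaningless t-test.

The Mantel test is the plain Pearson form — the correlation of
lower-triangle entries — with one-sided (greater) significance from jointly
permuting rows and columns of the second matrix:
\(p = (1 + \#\{r_{perm} \ge r_{obs}\})/(B + 1)\), 999 permutations by
default. Identical matrices therefore give exactly \(p = 1/(B+1)\), and
under independence the p-value is uniform (both are tested).

## What the synthetic generator emulates — and what it does not

`sim_gradient()` produces a seed-reproducible bundle mirroring the shape of
the study system: a birth–death pool (default 200 tips, Yule rate 1), eight
sites from 200 to 3700 m in 500 m steps, per-site richness unimodal with a
peak about 40% up the gradient (the canonical montane mid-elevation
maximum), temperature falling linearly at 0.54 °C / 100 m from 27.4 °C at
200 m, plant richness unimodal, and predator abundance decaying
monotonically (exponentially — deliberately not collinear with the linear
temperature profile, which would make the full model unidentifiable on
eight sites). The published lowland and timberline temperatures are not
exactly collinear with the stated lapse rate, so intercept and lapse are
free parameters with those values as defaults.

Five assembly regimes give known truth for every pipeline stage: `random`
(the calibration case — SES indices should be mean ≈ 0, sd ≈ 1),
`filtered` (high sites draw a configurable fraction of members from one
designated clade, the smallest clade holding ≥ 10% of the pool),
`overdispersed` (greedy max–min distance selection), `nested-attrition`
(each site a subset of the one below: all signal in \(\beta_{sne}\)) and
`range-turnover` (contiguous elevational windows: interval matrices on
which single-gap interpolation is provably a no-op).

The generator does *not* emulate sampling effort (light-trapping nights),
detection failure beyond what interpolation repairs, abundance structure
(everything is presence/absence), or phylogenetic signal in the traits that
drive ranges — ranges are assigned independently of the tree except in
`filtered` mode. Passing calibration and power tests on these data
therefore shows the statistics behave correctly under their own model, not
that any field dataset satisfies that model.

## Single-gap interpolation

Occurrence matrices from short-duration trapping under-record true
elevational ranges. A species absent at exactly one site whose immediate
lower and higher neighbours both record it is scored present there. The
strict reading — only absence runs of length exactly one — is the default;
a looser `any-flanked` mode fills flanked runs of any length but is opt-in,
and `off` disables filling. Terminal absences are never filled and the
operation is idempotent (both property-tested). Interpolation runs once,
before all alpha and beta analyses. Whether published per-site richness
tables are pre- or post-interpolation is often unstated, so
`community_summary()` can simply be called on both states.

## Numerical and design choices

* **Cophenetic distances** are computed in-package from the edge–tip
  incidence matrix (\(d_{ij} = w_i + w_j - 2\sum_e \ell_e m_{ei} m_{ej}\),
  one BLAS product), cross-checked in tests against `ape::cophenetic.phylo`
  and, via brute-force oracles, against explicit path enumeration. Tiny
  negative round-off is clamped to zero.
* **Null-model cost** scales as (iterations × sites × pool); MPD and PD are
  fully vectorized across sites per permutation, MNTD falls back to a
  per-site loop. The test-suite and acceptance calibrations use 199
  iterations with 1,000 replicate communities — SES moments are insensitive
  to ensemble size beyond ~200 iterations (the sd inflation factor is
  \(\approx \sqrt{1 + 1/B}\)) — while 999 remains the user-facing default.
* **Exhaustive mode** enumerates distinct subsets (\(\binom{n}{k}\)), not
  label permutations of which each subset occurs \(k!(n-k)!\) times; the
  two define the same distribution, but sample statistics are taken over
  the \(\binom{n}{k}\) distinct values. A guard refuses pools beyond
  \(10^5\) subsets.
* **Zero-length branches** are accepted (they arise from resolving
  constraint-induced polytomies); negative lengths are rejected.
  Ultrametricity is neither required nor enforced. Basal polytomies are
  treated as rooted at the basal node.
* **Seeds**: every stochastic function takes an explicit seed and restores
  the caller's RNG state (`withr::with_seed`); the pipeline requires one.

## Known limitations

Only presence/absence (unweighted) metrics are implemented; abundance
weighting is out of scope. The null model is label shuffling over the full
tree pool — frequency- or richness-weighted alternatives are not offered.
Multi-site (non-pairwise) beta decomposition is not implemented. p-values
beyond the SES scale are reported only as observed ranks within the null
ensemble. The orchestration layer is `run_pipeline()` plus these functions;
there is no shell executable.
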