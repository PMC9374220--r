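---
title: "Population graphs and BRIDES selection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population graphs and BRIDES selection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridesnet)
```

This vignette documents the statistical models behind `bridesnet`, the
parameters that matter, and the design decisions taken where the methods
literature leaves room.

## From genotypes to a population graph

Nodes are populations; edges express *conditional* genetic association.
The pipeline is:

1. **Encoding.** Each diploid multilocus genotype becomes a vector of
   allele counts, one column per (locus, allele) pair, entries 0/1/2.
   Missing genotypes are mean-imputed by default (`missing =
   "mean_impute"`), which keeps all individuals and biases each column
   toward its mean — conservative for covariance estimation; the
   alternative `drop_individual` discards any individual with a missing
   locus and is preferable when missingness is rare and random.
2. **Among-population covariance.** Columns are centered over all
   individuals, population centroids are averaged, and
   `G = C C' / p` with `C` the centroid matrix and `p` the number of
   allele columns. The derived squared distance between populations is
   `g_ii + g_jj - 2 g_ij`.
3. **Partial correlations and pruning.** With `R = cov2cor(G)` and
   precision `Ω = R⁻¹`, the partial correlation is
   `r_ij = -Ω_ij / √(Ω_ii Ω_jj)` and the edge-exclusion deviance is
   `EED_ij = -N ln(1 - r_ij²)`, referred to χ² with 1 df. An edge is
   retained iff `EED_ij` exceeds the critical value at level `alpha`
   (default 0.05, the conventional level; pruning is provably monotone in
   `alpha`). Retained edges get weight `√(g_ii + g_jj - 2 g_ij)`
   (conditional genetic distance scale); `sqrt_weights = FALSE` exposes
   the squared variant, since published analyses do not pin the transform
   down.

**Singularity of the centroid covariance.** Because the columns are
centered over all individuals, the population centroids satisfy one exact
linear constraint, so `G` (and `R`) is always rank-deficient by one. A
ridge-perturbed inverse is dominated by the null direction — in practice
every partial correlation saturates at −1 and nothing is ever pruned. The
package therefore inverts `R` on its informative subspace with a
Moore–Penrose pseudo-inverse whenever the smallest eigenvalue is below
`1e-8` of the largest, and uses a plain inverse otherwise (e.g. for
externally supplied, well-conditioned covariances). `N` in the deviance is
the total number of individuals, the sample size a Gaussian
graphical-model deviance test uses.

The pruned graph is **not** re-estimated when nodes are removed
downstream: subgraphs are induced subgraphs of the complete population
graph. Re-estimating after each removal would change the conditional
structure being compared and is left to the user who wants it (rebuild
from the reduced genotype table).

## Node-based metrics

Degree, betweenness, eigenvector centrality, clustering coefficient and
average path length are computed on the **unweighted topology**: on a
population graph the weights are distances with arbitrary scale, and
hop-count path lengths are the interpretable convention for these
summaries (a published 19-node graph with APL ≈ 2.7 is only consistent
with hop counts, given edge weights an order of magnitude larger).
Weighted betweenness is available behind `weighted = TRUE`. Betweenness is
unnormalized with fractional counting over tied shortest paths;
eigenvector centrality is scaled to max 1; the clustering coefficient of
degree-<2 nodes is reported as 0 by default (`cc_undefined = "na"` opts
into `NA`). Strength and the average inverse edge weight (AIEW) do use
the weights — AIEW is the standard proxy for migrant numbers. Average path
length over a disconnected graph defaults to the mean over reachable
pairs (with a warning), which is what node-removal scans need.

## BRIDES classification

For a subgraph `X_n` of the complete graph `X_all`, each unordered pair of
`X_n` nodes is typed by comparing `d_n` (shortest path within the induced
subgraph) with `d*` (shortest path in `X_all` forced through at least one
candidate node): breakthrough, roadblock, impasse, detour, equal,
shortcut. The six counts always partition the `C(n,2)` pairs.

Two contracts deserve emphasis:

* **Constrained length as a walk.** `d*` is `min_k d(u,k) + d(k,v)` over
  candidates `k`. With non-negative weights this is the exact optimum over
  walks that visit a required node; the realized route may revisit nodes.
  Forbidding revisits would make the problem NP-hard in general and
  changes nothing on the graphs this method targets.
* **Equality tolerance.** In hop mode lengths are integers and equality
  is exact. In weighted mode two lengths within relative `1e-9` are
  classified Equal, so floating-point noise cannot masquerade as a detour
  or shortcut.

## Weight models and stepwise selection

A weight model is six signed coefficients `(w_B, w_R, w_I, w_D, w_E,
w_S)`; the score of a BRIDES vector is the weighted count sum, and a
model's *complexity* is its number of nonzero weights. The five standard
models are S¹, B³S¹, B¹S³, B¹R₋₁D₋₁S¹ and B³D¹E²S³.

Selection is breadth-first greedy with **tie branching**: every added set
achieving the step's best normalized score survives, so all co-optimal
solutions of the minimal size are enumerated rather than an arbitrary tie
pick — node relabeling cannot change the reported solution set. Scores are
normalized by the score with *all* candidates added, which is therefore 1
by construction. Decisions in the corner cases:

* If the maximal score is ≤ 0 (possible with negative weights, or with S¹
  when no shortcut exists at all), normalization is undefined; the run is
  reported `no_solution` — no node is worth adding.
* Branches that plateau below 1 keep adding nodes; termination at the
  full candidate set is guaranteed when the maximum is positive.
* Greedy minimality is not exact minimality. The test suite runs an
  exhaustive subset oracle on small instances and requires agreement on
  at least 80% of them, documenting rather than hiding the gap; across
  the tested instances the greedy frontier finds the true minimum in the
  large majority of cases.

**Scenario subgraphs.** Proactive scenarios keep populations strictly
*better* than the threshold (heterozygosity > 0.72, estimated size > 75,
EO rank strictly better than BC); reactive keep the strictly *worse* side
(…< 0.72, < 75, strictly worse than B). EO ranks are ordered A > AB > B >
BC > C > CD > D. Boundary-equal populations fall in neither subgraph and
remain candidates — applied to the packaged 19-population table this
yields subgraph sizes 9, 9, 8, 10, 13 and 6, reproducing the published
6–13 range, which is what fixes the strict-inequality reading.

**Selection frequency.** Published per-node "selection" probabilities come
without a definition. The package defines, per node, frequency =
(runs in which the node appears in ≥ 1 co-optimal solution) / (runs in
which it was a candidate), with no-solution runs counting in the
denominator; the definition is recorded in the output so users can
recompute differently from the stored per-run results.

## The synthetic generator

`simulate_genotypes()` produces the data shape the pipeline assumes:
ancestral allele frequencies per locus from a symmetric Dirichlet(1),
population frequencies from `Dirichlet(ancestral · (1-F)/F)` — so `F`
plays the role of a drift/divergence parameter — and linear migration
mixing. Island mixing uses weight `2m` toward the ancestral pool so that
`m = 0.5` (every gene copy equally likely a migrant) is exact panmixia;
the two-cluster mode drifts two cluster-level frequency vectors first and
mixes populations toward their cluster mean (`2·m_within`) and the global
pool (`2·m_between`), emulating two shores weakly connected across a
barrier. Defaults (9 loci, 8 alleles, 25 individuals per population,
`F = 0.2`) match a typical microsatellite study of a long-lived
vertebrate.

What the generator does *and does not* establish: among-population
distance grows with `F` and collapses under panmixia, and with two weakly
connected clusters the top-betweenness node of the pruned graph sits on an
inter-cluster bridge in ≥ 80% of seeds — these are tested. It draws
genotypes independently within populations (no inbreeding, no null
alleles, no linkage), has no spatial structure beyond the two clusters,
and equal sample sizes; passing tests on it says the pipeline recovers
structure of this kind, not that field data meet these assumptions.
Pruned-graph *density* turns out to be largely insensitive to the
migration rate under this generator (migration shrinks the covariance
signal rather than adding conditional dependencies), so no density trend
is asserted.

## Numerical choices and problem sizes

* Pseudo-inverse threshold `1e-8` (relative smallest eigenvalue);
  weighted-equality tolerance `1e-9`; normalized-score termination
  tolerance `1e-9`.
* Dirichlet draws via normalized gammas, with a zero-sum guard for
  extreme concentrations.
* Test problem sizes are chosen so every brute-force oracle is exact and
  the whole suite runs in about a minute: path/betweenness oracles
  enumerate all simple paths on graphs of ≤ 8–10 nodes (100 replicates),
  count conservation uses 1000 random instances of ≤ 10 nodes, the
  exhaustive selection oracle enumerates all candidate subsets on 50
  instances with ≤ 4 candidates, and generator properties use 20 seeds
  per condition.

## Known limitations

* The covariance construction's absolute scale is not comparable across
  encodings; only the pruning decisions and relative distances matter.
* Greedy selection can overshoot the true minimal node count on adversarial
  topologies (documented by the exhaustive oracle, observed in under 20%
  of small random instances).
* Directed gene flow, paths constrained through ≥ 2 required nodes, and
  per-step graph re-estimation are out of scope.
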