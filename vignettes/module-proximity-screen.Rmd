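---
title: "Disease modules and network-proximity drug screening with modprox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease modules and network-proximity drug screening with modprox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modprox)
```

## The problem

Complex diseases rarely map to a single gene. Proteins and metabolites
perturbed by a disease tend to form a connected, unusually dense
neighborhood of the interactome — a *disease module* — and drugs whose
targets sit close to that module are plausible candidates for repurposing.
`modprox` implements this two-stage analysis on a heterogeneous
metabolite–protein background network:

1. **Module discovery.** Differential omics (a transcript layer and a
   metabolite layer from a two-group design) provide node scores; a
   stochastic, score-weighted growth algorithm run many thousands of times
   yields an ensemble of candidate modules, condensed into one consensus
   disease module.
2. **Drug screening.** Each drug's target set is scored by its
   closest-distance network proximity to the module, normalized against a
   degree-preserving permutation null; strongly proximal drugs
   (z < −2.5, p < 0.01) are flagged as repurposing candidates.

Everything runs on synthetic data shipped with the package, so the whole
pipeline is testable without any external database.

## The background network

The arena is an undirected simple graph whose nodes are proteins or
metabolites: a protein–protein interaction layer merged with a
metabolite–enzyme layer (`merge_networks`). Self-loops and duplicate edges
are dropped at load. All downstream computation is restricted to the
largest connected component (`largest_connected_component`), which
guarantees finite shortest-path distances; the component restriction is
logged. Metabolite identifiers conventionally carry a namespace prefix
(`cpd:`) so the two layers cannot collide.

## Node scores

The metabolite filter follows the standard metabolomics triage: VIP > 1
(variable importance in projection from PLS-DA, consumed as an input
column, never computed here), absolute linear fold change > 1.2, and a
two-sided Mann–Whitney U p < 0.05. The rank-sum p-value is exact
(enumeration) when both groups have at most 8 tie-free observations and
otherwise uses the normal approximation with tie and continuity
corrections.

The transcript filter is absolute fold change > 2 with
Benjamini–Hochberg FDR < 0.01. The per-gene test is pluggable. The default
is the moderated t-statistic (empirical-Bayes variance shrinkage via
limma): at the small group sizes typical of animal experiments
(n = 6 per group here), rank-based tests cannot reach FDR < 0.01 at all —
the exact two-sided Mann–Whitney p-value has a floor of
2/choose(12, 6) ≈ 0.0022, which after BH adjustment across hundreds of
features with tens of true effects never clears 0.01. A rank-sum option
(`test = "wilcoxon"`) remains available for larger designs.

Fold changes are ratios of group arithmetic means on the linear scale;
zeros are imputed with half the smallest positive value of the table.

Each selected feature maps to its network node and contributes
s(i) = |log2 FC| — direction-free, since the growth algorithm rewards
large scores and both strong up- and down-regulation are equally
informative about module membership. When a gene and a metabolite map to
the same node the larger score wins. Unscored network nodes get s(i) = 0
and *do* enter the global mean μ, which is therefore the background mean
score of the network.

## Module growth

A module M of size m with running score Z_m considers its first-order
neighbors. Adding node i updates the score by the recursion

Z_{m+1}(i) = (s(i) − μ + Z_m · m) / (m + 1),

whose closed form is the mean of s − μ over members. Node i is *eligible*
if Z_{m+1}(i) > Z_m strictly and its connectivity significance

P(i) = Σ_{k = k_m}^{k_i} C(m, k) C(N−m, k_i−k) / C(N, k_i)

is below α = 0.01, where k_i is i's degree and k_m its number of neighbors
already in M — the hypergeometric tail probability of i being at least as
connected to M by chance. One eligible node is drawn with probability
s(i)/Σ s(j) over the eligible set and appended; growth stops when no
candidate remains eligible. P(i) is evaluated in log-gamma space and
clamped to [0, 1].

### Score normalization

The package offers two variants of the running score. The recursion above
(`variant = "mean"`) keeps Z_m equal to the members' mean centred score.
That quantity is useful as a bookkeeping identity, but it is a poor
*ranking* criterion for an ensemble: a singleton module sitting on the
single best-scoring node has Z = max(s) − μ, which no multi-node module
can exceed, so the top of a ranked ensemble degenerates to single nodes.
The default (`variant = "sqrt"`) therefore normalizes the centred score
sum by √m instead of m — the normalization used by the module-growth
methodology this algorithm derives from — which rewards modules for
accumulating many high-scoring members while still penalizing dilution.
Both variants enforce the same strict-increase and connectivity rules.

### Seeding, ensembles, consensus

Seeds are drawn uniformly with replacement from nodes with s(i) > 0
(configurable to all nodes with `seed_pool = "all"`): a zero-score seed can
never be drawn into any other module and contributes a size-1 module of
negative score, so positive-score seeding simply avoids wasted draws. The
seed itself is admitted unconditionally (Z_0 = 0; the growth rules
constrain only additions). Zero-score candidates carry zero selection
probability and are never added.

The ensemble (default 10,000 modules; 100,000 reproduces the
interactome-scale setting, 2,000 is used in the package's tests) is ranked
by score, ties broken toward smaller modules and then lexicographically
smaller seed ids. The consensus module pools the top 1% of modules, counts
node occurrences, ranks nodes by frequency (ties: higher s(i), then id)
and keeps the top `node_frac` share of the distinct pooled nodes.

`node_frac` deserves a note. At interactome scale an ensemble explores a
large halo around the signal (thousands of distinct nodes in the top 1%),
and keeping a small share — 5% — of the most frequent ones trims the
incidental periphery. At benchmark scale (2,000-node networks, ~60 scored
nodes) the ensemble concentrates almost entirely on the signal
neighborhood, and any small share would truncate the module to a handful
of nodes. The default is therefore `node_frac = 1` (keep every node of the
top modules); 0.05 is the recommended setting for very large ensembles on
full interactomes.

## Network proximity and the drug screen

For a drug with target set T and module S, the closest-measure distance is

d(T, S) = (1/|T|) Σ_{t∈T} min_{s∈S} d(t, s),

with d(t, s) the unweighted shortest-path hop count. Significance comes
from a degree-preserving permutation null: nodes are sorted by degree into
contiguous bins of at least `min_bin_size = 100` nodes (equal degrees
never split; an undersized trailing bin merges backwards), and each
permutation replaces T by a random set drawn bin-wise, matching T's size
and degree profile. Exact degree matching is infeasible for hubs; binning
is the established convention for this measure. The z-score is
(d_obs − mean(d_r))/sd(d_r) over `n_perm = 1000` permutations (200 in
tests), and the empirical p-value is the one-sided small-distance tail
with an add-one and mid-p tie correction,

p = (1 + #[d_r < d_obs] + ½·#[d_r = d_obs]) / (n_perm + 1),

so p is never exactly 0 — a permutation p of 0 is not attainable from
finitely many permutations. The mid-p treatment matters because closest
distances live on the lattice of multiples of 1/|T|; counting the whole
tie mass would make p conservative and visibly non-uniform under the
null.

Only the target set is randomized by default (`randomize =
"targets-only"`): the null then compares like with like and is exchangeable
by construction. Randomizing the module as well (`randomize = "both"`) is
offered, but a connected module and its scattered degree-matched
replacement cover the network differently, which shifts the null and
mis-calibrates the empirical p (we measure a Kolmogorov–Smirnov distance
from uniformity of ~0.2 under double randomization, versus ~0.05 under
target-only). Candidates are flagged by z < −2.5 *and* p < 0.01, and the
result table is sorted by z ascending.

If the permutation distances are all identical (sd = 0) the z-score is
reported as missing and the row flagged degenerate rather than inventing a
value; the empirical p is still valid. On networks up to a few thousand
nodes the screen precomputes the all-pairs distance matrix once
(8·N² bytes); beyond that it falls back to per-drug BFS.

## The synthetic benchmark

`synth_bundle()` generates every input from one seed:

* **Background network** — 1,800 proteins grown by preferential attachment
  (3 edges per new node), plus 200 metabolites each wired to 1–8 enzymes
  with degree-biased choice; simple, connected, heavy-tailed. The 2,000
  node scale keeps a full pipeline run in minutes on one CPU while
  preserving the hub structure that degree-matched sampling must cope
  with.
* **Planted module** — a connected 60-node subgraph grown by
  edge-weighted neighbor expansion, then densified with random
  within-module edges to a mean within-module degree of 4
  (`densify_module`). Disease modules are *denser* than random subgraphs —
  reported metabolite–protein disease modules run at roughly 2 edges per
  node — and that excess interconnectivity is exactly the signal the
  hypergeometric connectivity test detects. Without densification a
  planted set grown in a sparse scale-free background is nearly tree-like
  (mean degree ≈ 2), carries no connectivity signal, and no
  connectivity-based method could or should recover it: at N = 2,000 a
  candidate with a single edge into the module already fails P < 0.01 once
  m > 6.
* **Omics tables** — log-normal intensities, 6 samples per group, each
  planted node carrying exactly one feature with a ±1.8 log2 shift (sign
  random, echoing that real perturbations mix depletion and accumulation),
  Gaussian log2 noise σ = 0.25; 500 gene and 150 metabolite features in
  total. The metabolite layer carries a VIP surrogate (scaled absolute
  standardized mean difference) so the VIP > 1 gate is exercised.
* **Drug library** — 20 proximal drugs (≥80% of 2–6 targets inside the
  planted module, the rest on its first-order neighbors, so d ≤ 0.2) and
  80 distal drugs (degree-matched targets at distance ≥ 2, so every
  distance term is ≥ 2).

What the generator deliberately does **not** emulate: peak-level LC–MS
artefacts, sequencing count noise, correlated features, annotation
ambiguity, or the curated structure of real interactomes. Passing the
benchmark shows the machinery is correct and calibrated, not that any
particular real dataset will yield a module of a given size.

## Numerical and degenerate-input choices

* Hypergeometric sums in log-gamma space, clamped to [0, 1]; invalid terms
  (k > m or k_i − k > N − m) contribute zero.
* Strict inequalities exactly as the screening rules state them
  (fold change > threshold, p < threshold, Z_{m+1} > Z_m, z < −2.5).
* Ties broken deterministically everywhere (module ranking, consensus node
  ranking, screen ordering), so a fixed seed reproduces every output byte
  for byte; one master seed fans out to fixed per-stage child seeds so
  stages can be rerun independently.
* Empty module after filtering, no positive-score seed, unmapped drugs,
  unreachable targets and degenerate permutation nulls all fail loudly or
  are flagged, never silently imputed.

## Problem sizes used by the package's own checks

The test suite and the acceptance script run the benchmark at 2,000-node
networks with ensembles of 2,000–10,000 modules and screens of 100–200
drugs at 200–1,000 permutations; published interactome-scale settings
(100,000 modules, 1,000 permutations) are one flag away
(`interactome_scale = TRUE`) and change nothing structurally.

## Known limitations

* The consensus is a node set; edge-level confidence is not assessed.
* Degree binning preserves degree only at bin resolution; extremely
  hub-heavy target sets may be matched loosely.
* The gene-layer default (moderated t on log2 intensities) assumes
  approximately log-normal expression; raw counts should be normalized
  upstream or screened with a count model outside this package.
* VIP is trusted as given; no PLS-DA is fitted.
* Recovering a *specific* published module or drug ranking requires the
  original interactome build and drug–target extraction, which are not
  shipped.
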