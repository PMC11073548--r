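---
title: "Topological inference on weighted networks: methods and design notes"
author: "topofilt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological inference on weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topofilt)
```

## The model

A brain network — or any relational system — is represented as a weighted
graph $G = (V, w)$ on $q$ nodes with symmetric edge weights $w_{ij}$,
giving $r = (q^2 - q)/2$ potential edges. Rather than fixing one threshold
and studying a single binary graph (whose topology can change drastically
with the threshold), we study the whole *graph filtration*: the nested
family of binary graphs $G_\epsilon$ keeping edges with $w_{ij} > \epsilon$
as $\epsilon$ increases. The graph filtration is the 1-skeleton restriction
of the Rips filtration, which keeps the computation tractable for resampling
inference.

Two topological invariants summarise each $G_\epsilon$: the number of
connected components $\beta_0(\epsilon)$ and the number of independent
cycles $\beta_1(\epsilon)$. Over a graph filtration $\beta_0$ only grows and
$\beta_1$ only shrinks, and each edge weight is an *event* of exactly one
kind:

* weights on a **maximum spanning forest** of $G$ are **births** of
  components — the *birth set* $B_G$, the 0D persistence diagram;
* every remaining weight **kills a cycle** — the *death set* $D_G$, the 1D
  persistence diagram.

The two sets partition the edge-weight multiset (a uniqueness that holds for
the *weights* even when ties make the forest itself non-unique). For a
connected complete graph, $|B_G| = q - 1$ and $|D_G| = (q-1)(q-2)/2$.
`birth_death_decompose()` finds the partition with one Kruskal pass over the
edges sorted by decreasing weight (union-find with path halving; ties broken
by ascending node indices so results are reproducible), i.e.
$O(q^2 \log q)$. One published description of this construction mentions
Kruskal "identifying the minimum spanning tree" while also equating the
birth set with the maximum spanning tree; the two statements are reconciled
here as Kruskal on negated weights, which is the maximum-spanning-forest
form implemented and tested. Similarly, a printed non-disjointness condition
($B_G \cap D_G \neq \emptyset$) alongside "decompose uniquely" is treated
as a typo for disjointness: the implementation enforces, and the tests
assert, an exact partition.

Betti curves come from the decomposition, not from per-threshold component
counting:
$$\beta_0(\epsilon) = q - \#\{b \in B_G : b > \epsilon\}, \qquad
  \beta_1(\epsilon) = \#\{d \in D_G : d > \epsilon\}
  = E(\epsilon) - q + \beta_0(\epsilon),$$
with $E(\epsilon)$ the surviving edge count (the Euler identity). The strict
inequality $w > \epsilon$ is kept bit-exactly; using $\ge$ would shift the
curves at event points, so the choice is part of the contract.

```{r betti-demo, eval = FALSE}
net <- random_complete_network(20, seed = 1)
bd <- birth_death_decompose(net)
plot(betti_curves(bd, default_threshold_grid(net, 100)))
```

## Topological distances

For graph filtrations the diagrams are one-dimensional sorted vectors, so
the 2-Wasserstein matching between two diagrams is simply order matching:

$$d_0(G_1, G_2) = \sum_i \big(b_i^{(1)} - b_i^{(2)}\big)^2, \qquad
  d_1(G_1, G_2) = \sum_i \big(d_i^{(1)} - d_i^{(2)}\big)^2,$$

with the combined distance $d = w_0 d_0 + w_1 d_1$ and default
$w_0 = w_1 = 1$. These are implemented exactly as displayed — sums of
squared differences without a square root. Whether the source formulation
intends the squared distance is ambiguous; we follow the displayed form
because the resampling inference below is invariant to monotone transforms,
and expose `root = TRUE` for users who want the metric version. Networks
whose diagrams differ in length are refused rather than padded: diagram
matching across unequal node sets is not defined for this filtration.

Two consequences worth knowing:

* **Scale**: multiplying all weights by $s$ multiplies $d_0, d_1$ by $s^2$.
* **Blindness to tree rearrangement**: two different trees with the same
  sorted edge weights have identical births and empty death sets, so
  $d_0 = d_1 = 0$. This is a feature for covariance networks and a genuine
  power limitation for tract-count connectivity, which is dominated by one
  large connected tree.

`pairwise_distances()` builds the $(m+n) \times (m+n)$ matrices `D0`, `D1`,
`D01` for two groups, decomposing each network once (not per pair);
`pairwise_matrix_distances()` provides the entrywise-L2 baseline that *does*
depend on node labelling.

## Group-difference inference

With within-group sum $l_W$ (each unordered pair once, both groups pooled)
and between-group sum $l_B$ (all $mn$ cross pairs), the test statistic is
the ratio $\phi = l_B / l_W$; large $\phi$ means cross-group distances
dominate. Its null distribution is approximated by resampling the *labels*
of the fixed distance matrix:

* `permutation_test()` redraws a full random relabelling each step;
* `transposition_test()` swaps one member of each group per step and
  updates $l_W$, $l_B$ incrementally. The update touches only the two
  swapped rows, i.e. $O(m+n)$ work per step, which is what makes
  $10^5$–$10^6$ resamples practical; a full relabelling is interspersed
  every 1,000 steps (configurable) to decorrelate the walk. The suite
  verifies the incremental state against from-scratch recomputation at
  every one of 10,000 steps to $10^{-10}$.

P-values are one-sided with the add-one rule,
$p = (1 + \#\{\phi^\ast \ge \phi\}) / (1 + N)$, so they are never zero and
the test is exact-in-expectation under exchangeability. Both tests record
their seed and null trace in the report object.

The parametric alternative, `z_test()`, compares mean between- and
within-group distances:
$$Z = \frac{\bar L_B - \bar L_W}
 {\sqrt{\mathbb{V}L_B / (mn) + \mathbb{V}L_W / (m(m-1) + n(n-1))}},$$
with moments over ordered pairs exactly as the denominators imply, tested
against the upper tail of $N(0,1)$ ($H_1$: between exceeds within). The
numerator uses means, consistent with those standard-error denominators.
Two caveats, verified by simulation in this package and documented rather
than patched:

* the within-group denominator counts *ordered* pairs although only half
  that many distinct distances exist, so under an i.i.d. exchangeable null
  the statistic is overdispersed (empirical sd $\approx 1.16$ at
  $m = n = 25$);
* distances sharing a network are dependent, which the variance derivation
  ignores; under a network-generated null the empirical sd is $\approx 0.85$.

`ks_normality_check()` reports the one-sample KS statistic and p-value of
simulated null $Z$ values against $N(0,1)$ so users can judge calibration
for their own problem sizes; with 1,000 simulated values the KS test has
enough power that these formula-level deviations are typically detected.
For trustworthy p-values we recommend the resampling tests; the Z-test is
provided as the fast parametric screen it is intended to be.

## Structural covariance networks

`correlation_network()` turns a subjects $\times$ nodes feature table
(Jacobian determinants, FA values, cortical thickness, ...) into a
correlation network (Pearson by default, Spearman optional), diagonal set
to zero. Since each group yields only one covariance network,
`jackknife_networks()` applies leave-one-out resampling: the $i$-th
replicate is the correlation network computed without subject $i$, giving
$m$ and $n$ per-subject networks that feed the distance and inference
machinery. Negative correlations are kept and filtered over the full weight
range by default — published displays typically threshold at positive
correlations only, but truncation is never stated, so it is opt-in via
`absolute = TRUE`. Jackknife replicates are strongly dependent by
construction; the label-resampling tests remain valid because they only
assume exchangeability of networks under the null.

## Synthetic generators and what they do (not) show

All generators are seeded and byte-reproducible.

**Point-cloud circle patterns** (`circle_pattern_networks()`): $n$ nodes at
evenly spaced arc-length positions along a planar pattern (default: a
figure-eight of two unit circles tangent at the origin), i.i.d. Gaussian
$N(0, 0.3^2)$ noise on both coordinates, connectivity = pairwise Euclidean
distance. Defaults (60 nodes, noise sd 0.3, 5 networks per group) are the
conditions of the rotation experiment this generator emulates. Because the
filtration removes *small* weights first, raw distances have the wrong
polarity ("far" would mean "strong"), so the weights default to the
affinity $\max(d) - d$; the farthest pair then maps to exactly 0 and drops
out as an absent edge (lengths stay equal across networks, so pairwise
distances remain well defined). The pattern geometry for the published
rotation experiment is not printed; the design here anchors the sampling
positions in the world frame and rotates the pattern beneath them. A
rotation is an isometry, so pairwise distances keep the same distribution
(all rotated groups are exactly topologically exchangeable), but the
rotation cyclically re-indexes the nodes, so entrywise matrix comparisons
see it unless the rotation is a symmetry of the pattern. For the
figure-eight, $0$ and $\pi$ are symmetric rotations ("horizontal"
networks agree entrywise in expectation) while $\pi/2$ and $3\pi/2$ give a
genuinely re-indexed ("vertical") family: the L2 baseline sees a
horizontal/vertical block structure that the topological distance provably
cannot.

**Matched-weight trees** (`matched_weight_trees()`): two trees of different
shape (path, star or binary) carrying an identical sorted multiset of
distinct weights — the worked example where $d_0 = d_1 = 0$ while the
entrywise L2 distance is positive.

**Factor-model tables** (`factor_model_table()`): node values
$\sqrt{\rho}\, f_s + \sqrt{1-\rho}\, e$, with subject factor
$f_s \sim N(0,1)$, so every node pair has population correlation $\rho$.
Raising $\rho$ makes the jackknife covariance networks denser at any
threshold: mean $\beta_0$ drops, mean $\beta_1$ rises — the directional
mechanism the group comparison is designed to detect.

What passing tests on these generators do **not** show: real covariance
networks have spatially structured (not exchangeable-equicorrelated)
dependence, heavy-tailed measurement noise, and hundreds of nodes; the
tract-count case adds sparsity and integer weights. The generators validate
algorithmic correctness, calibration under exchangeability, and directional
sensitivity — not field performance on imaging data.

## Numerical choices, problem sizes and limitations

* Edges with weight exactly 0 are absent by default (natural for count
  data); an explicit `mask` overrides. Disconnected inputs are allowed:
  births come from the maximum spanning *forest*, $|B_G| = q - c$.
* Tie-breaking: edge order (weight desc, $i$ asc, $j$ asc); diagrams depend
  only on weights, so any tie resolution gives the same distances.
* Asymmetry on ingest: exact symmetry required from constructors; file
  ingest repairs asymmetry up to $10^{-8}$ with a warning and refuses
  beyond.
* Negative variances from floating-point cancellation in `z_test()` are
  clipped to zero with a warning.
* Validation problem sizes were chosen to exercise the mathematics at desk
  scale: exhaustive spanning-tree enumeration at $q = 6$, igraph
  cross-checks to $q \le 20$, type-I calibration with 500 null replicates
  of $m = n = 10$ networks at 2,000 permutations each, and the rotation
  experiment at its stated 60-node/5-network design over 20 seeds. The
  decomposition itself is comfortable at $q$ in the hundreds (sorting
  $\sim q^2$ edges dominates).
* Out of scope: simplices of dimension $\ge 2$ (no Rips beyond the
  1-skeleton), persistence pairing beyond the value sets, landscapes/
  images/entropy, more than two groups, covariate adjustment. The ratio
  statistic is a single global test across all thresholds, so no
  multiple-comparison correction is applied or needed.
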