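# topofilt

Topological inference on weighted networks via graph filtration.

`topofilt` is for researchers comparing *groups* of weighted networks —
typically structural covariance networks built from neuroimaging features
(Jacobian determinants from tensor-based morphometry, fractional anisotropy
from DTI), but any symmetric connectivity matrices work. Instead of picking
one threshold and comparing the resulting binary graphs (results can flip
with the threshold), it compares the networks' topology across *all*
thresholds at once using persistent homology restricted to the graph
filtration.

## The method in brief

For a weighted graph $G = (V, w)$ on $q$ nodes, threshold at increasing
$\epsilon$, keeping edges with $w_{ij} > \epsilon$. Each edge weight is then
either

* a **birth** of a connected component — these weights form a maximum
  spanning forest of $G$ and the 0D persistence diagram $B_G$
  ($|B_G| = q - 1$ for a connected complete graph), or
* a **death** of a cycle — the remaining weights, the 1D diagram $D_G$
  ($|D_G| = (q-1)(q-2)/2$).

The *birth–death decomposition* is computed with a single union-find
Kruskal pass in $O(q^2 \log q)$; Betti curves follow directly:
$\beta_0(\epsilon) = q - \#\{b > \epsilon\}$,
$\beta_1(\epsilon) = \#\{d > \epsilon\}$.

Because the diagrams are sorted value vectors, the 2-Wasserstein distance
between two networks reduces to order matching:

$$d_0 = \sum_i (b_i^{(1)} - b_i^{(2)})^2,\quad
  d_1 = \sum_i (d_i^{(1)} - d_i^{(2)})^2,\quad
  d = w_0 d_0 + w_1 d_1 \ (w_0 = w_1 = 1).$$

Groups are compared through the ratio $\phi = l_B / l_W$ of between- to
within-group distance sums, with significance from label permutation of the
fixed pairwise distance matrix — either full permutations or the scalable
online **transposition test** ($O(m+n)$ incremental updates per swap, a
full permutation interspersed every 1,000 steps) — plus a parametric
Z-statistic on between- vs within-group distances. Single-per-group
covariance networks are turned into samples by leave-one-out jackknife
resampling.

## Worked example

Two groups of 20 subjects measured at 25 nodes; the "case" group has a
higher inter-node correlation (0.6 vs 0.3), i.e. more homogeneous features
and therefore denser covariance structure:

```r
library(topofilt)
tab_ctrl <- factor_model_table(n_subjects = 20, q = 25, rho = 0.3, seed = 11)
tab_case <- factor_model_table(n_subjects = 20, q = 25, rho = 0.6, seed = 12)
nets_ctrl <- jackknife_networks(tab_ctrl)   # 20 leave-one-out networks
nets_case <- jackknife_networks(tab_case)
gd <- pairwise_distances(nets_ctrl, nets_case,
                         group_names = c("control", "case"))
transposition_test(gd, n_transpositions = 20000, seed = 99)
#> Topological ratio test (transposition, 20000 resamples)
#>   groups: m = 20, n = 20
#>   phi = 130.326,  p = 4.99975e-05 (one-sided, add-one rule)
z_test(gd)
#> Z-test on between- vs within-group distances (m = 20, n = 20)
#>   mean within = 0.275938, mean between = 34.1639
#>   Z = 132.142,  one-sided p = 0
```

The between-group distances dwarf the within-group ones
($\phi \approx 130$), and the transposition test's add-one p-value is at
its floor $1/20001$: the topological difference induced by the correlation
shift is detected decisively. Betti curves visualise the mechanism — the
high-correlation group sits lower in $\beta_0$ (fewer components) and
higher in $\beta_1$ (more cycles):

```r
bd <- birth_death_decompose(nets_ctrl[[1]])
bd
#> Birth-death decomposition: 25 nodes, 1 components
#>   births (0D diagram): 24 values
#>   deaths (1D diagram): 276 values
plot(betti_curves(bd, default_threshold_grid(nets_ctrl[[1]], 100)))
```

A command-line front end wrapping the same functions lives at
`inst/cli/topofilt.R` (subcommands `decompose`, `betti`, `dist`, `test`,
`covnet`, `simulate`, `pipeline`), and `run_pipeline()` executes the whole
chain (feature table → jackknife → decomposition → distances → inference →
artifacts) from a YAML config.

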