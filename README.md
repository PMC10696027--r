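# csntox

Chemical space network (CSN) criticality analysis for toxicity
read-across.

## The problem

Small-molecule toxicity endpoints with scarce, noisy labels — such as
developmental toxicity — are often analysed through *chemical space
networks*: graphs whose nodes are molecules and whose edges connect
pairs with structural similarity above a cut-off. The choice of that
cut-off shapes everything downstream (communities, centralities,
read-across predictions), and picking it by hand is arbitrary. This
package implements a statistical-mechanics answer: sweep the threshold,
compare the CSN against matched Erdős–Rényi (ER) null graphs, and take
the cut-off at which the network undergoes its percolation-like phase
transition — signalled by the peak in betweenness centrality and the
onset of the giant component.

## What it computes

- **Similarity.** The pairwise MCS-Tanimoto similarity
  `s = m / (|A| + |B| − m)`, where `m` is the heavy-atom size of the
  maximum common connected (induced) subgraph of the two
  hydrogen-suppressed molecular graphs, computed by an exact
  branch-and-bound search with element-exact atom matching and
  order-exact bond matching (aromatic is its own order). Values at or
  below a floor (default 0.3) are treated as uninformative and not
  stored.
- **Criticality.** For each threshold `t` on a grid, the unweighted CSN
  with edge count `E`, `E_max = N(N−1)/2` and connection probability
  `p = E/E_max` is compared against an ensemble (default 20 replicates)
  of uniform `G(N, E)` ER graphs — same order, exactly the same number
  of edges. Tracked diagnostics: degree, unnormalised betweenness,
  eigenvector centrality, giant-component fraction and degree
  assortativity. The critical threshold is the betweenness peak (giant
  onset and assortativity peak are available as alternative criteria).
- **Communities.** Louvain modularity maximisation at criticality, plus
  a descriptor screen: near-constant descriptors are dropped, then each
  descriptor is tested across the top-3 communities with all pairwise
  Mood's median tests under Bonferroni correction at α = 0.01.
- **Read-across classification.** A similarity-weighted neighbour vote
  (`score = Σ s·y / Σ s`, toxic = 1) evaluated by stratified 80%
  hold-out cross-validation iterated 100 times, reporting accuracy,
  sensitivity, specificity and F1 with toxic as the positive class.
- **Synthetic data.** A scaffold-family generator (shared cores with
  random decorations, per-family labels, label noise) and an abstract
  planted-block similarity generator, so the whole pipeline is testable
  without any external dataset.

## Worked example

```r
library(csntox)

mols <- three_archetypes(seed = 1)   # 3 planted scaffold families
mols
#> <molecule_set> 60 molecules (44 toxic, 16 nontoxic, 0 unlabelled)

store <- pairwise_similarity(mols, floor = 0.3)
store
#> <similarity_store> 60 molecules, 596 pairs > floor 0.3 (0 timeouts)

sweep <- threshold_sweep(store, n_er = 20, seed = 11)
crit  <- detect_critical_point(sweep, "betweenness_peak")
crit
#> <critical_point> t_crit = 0.79, p_crit = 0.05424 (betweenness_peak)

part <- louvain_partition(build_network(store, crit$t_crit), seed = 2)
part
#> <community_partition> 10 communities, Q = 0.6137, top sizes: 15, 13, 11, 6, 5,
#>   connected fraction = 0.95

cv <- holdout_cv(store, t = crit$t_crit, iters = 100, seed = 4)
cv
#> <classification_report> t = 0.79, 100 iterations (80% stratified hold-out)
#>      accuracy sensitivity specificity     f1
#> mean   0.9325           1      0.7300 0.9581
#> sd     0.0539           0      0.2155 0.0328
#> mean unclassifiable test nodes per iteration: 1.06
```

Reading the output: the sweep finds the phase transition at Tanimoto
similarity 0.79, where the planted families are thinned to
barely-connected clusters; Louvain there returns family-pure
communities (top sizes 15/13/11) with modularity 0.61 while 95% of
nodes remain connected; the neighbour vote classifies held-out
molecules with 93% accuracy and perfect sensitivity, with the lower
specificity typical of similarity-based read-across when the negative
class is small and heterogeneous.

`run_pipeline(run_config(mols, "out/"))` chains all stages (curation →
similarity → sweep → communities → screen → classification) and writes
per-stage CSV/JSON artifacts plus a checksummed `manifest.json`;
reruns with the same config are bit-identical.

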