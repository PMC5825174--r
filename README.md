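# nemacge

Hub connectivity and correlated gene expression in neuronal connectomes.

Across nervous systems, a minority of highly connected hub neurons are
more densely interconnected among themselves than degree-matched chance
predicts — a *rich club*. In the *C. elegans* somatic connectome (279
neurons, directed chemical synapses plus bidirectional gap junctions),
the hubs are mostly command interneurons, and a central question is
whether they also share a transcriptional signature: do connected hubs
have more similar gene-expression profiles than other neuron pairs, and
which genes drive that similarity? This package implements the full
statistical toolkit for that analysis:

- **Rich-club detection**: the rich-club coefficient
  φ(k) = 2·E&gt;k / (N&gt;k·(N&gt;k − 1)), normalized against degree-preserving
  rewiring nulls (directed double-edge swaps, 50 per edge) with
  permutation p-values per degree threshold, hub-distance statistics,
  and weighted variants.
- **Correlated gene expression (CGE)**: the mean square contingency
  (phi) coefficient r_φ between binary expression profiles, with
  bilateral-homolog masking, alternative measures (Jaccard, Yule's Q, a
  mutual-expression probability index), and an annotation-density bias
  simulation.
- **Edge-class comparisons**: median CGE of rich / feed-in / feed-out /
  peripheral connections across hub thresholds, with one-sided rank-sum
  flags.
- **Gene-contribution scoring**: a binomial upper-tail score
  p⁽ᵃ⁾ = P(X ≥ m), X ~ Binomial(n, p_class), per gene, with an n ≥ 10
  quality filter, BH-FDR correction, hit calling at 10⁻⁴, and
  hypergeometric over-representation analysis of hit lists.
- **Driver analyses**: rank-sum, Welch and Spearman comparisons over
  module, birth-time, lineage and neuron-class groupings, plus
  composition-matched permutation nulls (random neuron sets matching a
  target set's neurotransmitter or anatomical composition).
- **Louvain consensus modularity** and distance statistics
  (equiprobable binning, bounded exponential fits A·exp(−λd) + B).
- A **synthetic-data generator** reproducing the dataset's statistical
  structure (spatial clusters, distance-decaying connectivity, a planted
  rich club, sparse binary expression with planted hub genes, bilateral
  homolog pairs), so the entire pipeline runs and is tested end-to-end
  without any download.

See the methods vignette (`vignettes/nemacge-methods.Rmd`) for the
models, assumptions, parameter defaults and limitations.

## Worked example

```r
library(nemacge)

ds  <- simulate_dataset(synth_config(seed = 1))
ds$connectome
#> connectome: 279 neurons, 1699 chemical records, 391 gap records
#>   2481 directed connections, 1959 connected unordered pairs

deg   <- degree_sequence(ds$connectome)
k_thr <- sort(deg$k, decreasing = TRUE)[17]   # top-16 hub rule -> 37

rc  <- normalized_rich_club(ds$connectome, n_null = 500, seed = 1)
rc[rc$k == k_thr, c("k", "N_gt", "phi", "phi_rand_mean", "phi_norm", "p_perm")]
#>   k N_gt phi phi_rand_mean phi_norm p_perm
#>  37   16 0.7         0.365     1.92  0.002
```

At the hub-defining threshold the 16 hubs have link density 0.70 against
0.365 expected under degree-matched rewiring — a normalized rich-club
coefficient of 1.92 with permutation p = 0.002; the significant regime
spans k = 28–51 and covers the planted hubs.

```r
bil <- bilateral_pairs(ds$neurons)
cge <- cge_matrix(ds$expression, "r_phi", bilateral_pairs = bil)
hubs <- label_hubs(deg, k_thr)
is_hub <- setNames(hubs$is_hub, hubs$neuron)
cp <- connected_pairs(ds$connectome)
compare_pair_sets(cge,
                  cbind(cp$a, cp$b)[ is_hub[cp$a] &  is_hub[cp$b], ],
                  cbind(cp$a, cp$b)[!is_hub[cp$a] & !is_hub[cp$b], ],
                  test = "ranksum", alternative = "greater")
#> ranksum (greater): statistic = 9.135e+04, p = 2.05e-11
#>   medians 0.03438 vs -0.003421 (n = 82, 1556)
```

Rich connections have markedly higher median CGE than peripheral ones
(0.034 vs −0.003, one-sided rank-sum p ≈ 2×10⁻¹¹). The binomial gene
score then ranks the genes driving the effect:

```r
gs <- score_genes(ds$expression, ds$connectome,
                  "hub_involved_vs_peripheral", k_threshold = k_thr,
                  exclude_pairs = bil)
head(gs[order(gs$p_a), c("gene", "m", "n", "p_class", "p_a", "p_corr", "hit")], 5)
#>   gene  m  n p_class      p_a   p_corr  hit
#>  g0358 78 92   0.201 2.77e-40 4.46e-38 TRUE
#>  g0921 63 70   0.201 3.47e-36 2.80e-34 TRUE
#>  g0582 61 68   0.201 6.94e-35 3.73e-33 TRUE
#>  g0014 59 65   0.201 1.82e-34 7.34e-33 TRUE
#>  g0915 61 69   0.201 4.80e-34 1.55e-32 TRUE
```

All five top-scoring genes are planted hub genes: a gene expressed in
both neurons of 78 pairs, 92 of whose matches could have fallen anywhere,
lands in hub-involved connections far more often than the class
proportion p_class = 0.20 allows by chance.

`run_pipeline(pipeline_config(...))` chains all stages (simulation or
TSV inputs → spatial curves → rich club → modularity → CGE → edge-class
and driver comparisons → gene scoring) and writes per-stage TSVs plus a
summary JSON.

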