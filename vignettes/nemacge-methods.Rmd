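---
title: "Methods: hub connectivity and correlated gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hub connectivity and correlated gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemacge)
```

## The scientific problem

Neuronal connectomes across species share a motif: a minority of
high-degree hub neurons that are more densely interconnected among
themselves than degree-matched chance predicts (a *rich club*). In the
*C. elegans* somatic nervous system — 279 neurons joined by directed
chemical synapses and electrical gap junctions — the hubs are
predominantly command interneurons governing locomotion. This package
implements the statistical machinery for asking whether such hubs also
share a transcriptional signature: whether connected hub pairs have more
similar binary gene-expression profiles than other neuron pairs, which
genes drive that similarity, and whether candidate confounders (space,
birth time, lineage, neurotransmitter, module membership, neuron class)
can explain it.

## The network model

The connectome is the combined directed binary graph: each chemical
synapse record is one directed edge, each gap junction is treated as a
bidirectional connection. Degree is `k = k_in + k_out`, with each gap
junction contributing to both the in- and out-degree of both endpoints;
a pair linked by both mechanisms contributes once per mechanism to `k`
but once as a "connected pair" in pair-level sets. Weights (synapse
counts) are retained as metadata and only used by the weighted rich-club
variant.

At a threshold `k` every neuron is a *hub* (degree > k, strictly) or a
nonhub, and every directed connection is *rich* (hub to hub), *feed-in*
(nonhub to hub), *feed-out* (hub to nonhub) or *peripheral*
(nonhub to nonhub). These four classes partition the directed edge set
at every threshold.

### Rich-club coefficient and nulls

The rich-club coefficient is the link density among nodes above a degree
threshold,

$$\phi(k) = \frac{2E_{>k}}{N_{>k}(N_{>k}-1)},$$

where $N_{>k}$ counts nodes with degree $> k$. Because the printed
factor 2 is only consistent with a directed graph when $E_{>k}$ counts
*unordered connected pairs*, that is the default (`edge_count =
"pairs"`, keeping $\phi \le 1$); a directed-edge density mode
(`E/(N(N-1))`) is provided as an option since the source convention for
directed networks is ambiguous. $\phi(k)$ rises mechanically with `k`,
so it is normalized by the mean coefficient of an ensemble of
degree-preserving rewired networks,
$\Phi_{\mathrm{norm}}(k) = \phi(k) / \langle \phi_{\mathrm{rand}}(k)\rangle$,
with a permutation p-value per threshold computed directly from the null
ensemble using the add-one estimator $(1 + r)/(n_{\mathrm{null}} + 1)$,
which can never return zero. The rewiring null is the standard directed
double-edge swap (as in the Brain Connectivity Toolbox `randmio_dir`),
run at an average of 50 swaps per edge; it preserves both in- and
out-degree sequences exactly and forbids self-edges and duplicate edges.
Gap junctions enter the rewiring as two directed edges swapped
independently by default; an option preserves their reciprocity, since
the source convention is not documented. One ensemble is generated per
run and reused across all thresholds.

The weighted variant divides the total weight among supra-threshold
nodes by the sum of the equally many largest weights anywhere in the
network, against either a weight-shuffling null (topology fixed) or a
rewire-plus-shuffle null.

### Modularity

Community structure uses Louvain on the symmetrized (undirected) graph —
Louvain modularity is not well defined for directed graphs and the
reference analyses applied undirected routines to this network —
repeated with distinct sub-seeds, combined through a consensus step: a
module-coassignment agreement matrix weighted by each run's modularity
Q, thresholded at `tau = 0.4` (a common consensus-clustering default,
exposed as a parameter since the source procedure's constants are not
published), then re-clustered iteratively until all runs agree. Module
ids are relabeled contiguously, size-descending, ties broken by smallest
original id. Externally derived partitions (e.g. a nine-module
Erdős–Rényi mixture-model decomposition) are consumed from TSV, never
re-derived.

## Correlated gene expression (CGE)

Expression is a binary neurons × genes indicator matrix; 0 means "not
expressed *or* unknown", which is why the data are sparse and why
annotation-density robustness matters. Pairwise similarity is the mean
square contingency (phi) coefficient

$$r_\phi = \frac{n_{11}n_{00} - n_{10}n_{01}}
{\sqrt{n_{1\bullet}\,n_{0\bullet}\,n_{\bullet 0}\,n_{\bullet 1}}} \in [-1, 1],$$

computed from the 2×2 contingency counts of the two profiles. A zero
marginal (a neuron with no annotations, or annotated everywhere) makes
$r_\phi$ undefined; such pairs are flagged and propagated as missing —
never imputed as 0 — and excluded from medians and tests, because any
imputation rule would bias the medians. Jaccard, Yule's Q and a
probability-of-mutual-expression index (`p_match`) are provided for
sensitivity analysis. `p_match` is constructed here as one minus the
fixed-marginals hypergeometric upper-tail probability of observing at
least the realized number of co-expressions; it satisfies the
documented requirements for such an index (monotone in mutual
expression, insensitive to annotation density) and is labelled a
construction of this package.

Bilateral homolog pairs (left/right mirror neurons) have near-identical
expression profiles and are masked from every CGE analysis so that they
cannot drive group differences; masks carry reason codes
(`self`, `bilateral`, `undefined`) and masked entries are written as
`NA`, never 0.

The `bias_simulation()` grid quantifies annotation-density bias: pairs of
random binary vectors varying only in their proportion of ones. Under
independence the overlap count given both annotation counts is
hypergeometric, which the simulation draws directly — an exact shortcut
for the vector-pair simulation it summarizes. The phi coefficient is
unbiased across the density grid; Jaccard and Yule's Q are strongly
density-driven, which is the reason $r_\phi$ is the default measure.

## Spatial statistics

Distances are 2-D Euclidean in μm (the positional data are 2-D; no
axon-trajectory distances). Curves use equiprobable (quantile) bins —
counts differing by at most one, ties going to the lower bin
deterministically — with 10 bins for connection probability (ordered
pairs within a source-region to target-region stratum) and 7 for CGE
(unordered pairs, masked values excluded). Exponential trends
$f(x) = A e^{-\lambda x} + B$ are fitted to bin centers by bounded
Levenberg–Marquardt least squares with $A \ge 0$, $\lambda \ge 0$,
initialized at $A_0 = \max - \min$, $B_0 = \min$,
$\lambda_0 = 1/\mathrm{median}(x)$, tolerance $10^{-8}$ (the fitting
procedure is this package's choice; only the functional form is given by
the source analyses). `residualize()` subtracts the fitted trend —
mainly to demonstrate that residualizing a trend driven by a few nearby
high-CGE pairs produces artifactual negative values, so the package does
*not* residualize CGE by default.

## Gene-contribution scoring

For a contrast between two disjoint classes of neuron pairs (connected
vs unconnected; or connected pairs involving a hub vs peripheral
connections), each gene is scored by the probability of observing at
least its number of class matches under a binomial null:

$$p^{(a)} = P(X \ge m), \quad X \sim \mathrm{Binomial}(n, p_{\mathrm{class}}),$$

where a *match* means the gene is expressed in both neurons of a pair,
`m` counts matches on the class of interest, `n` matches over both
classes, and $p_{\mathrm{class}} = n_{\mathrm{class}}/M$ is the class
proportion of the pair universe, recomputed from the data after
bilateral exclusion rather than hard-coded. The tail is computed with
the binomial survival function rather than a literal
$1 - \sum$ (which loses precision to cancellation for large `n`), and
`m = 0` returns exactly 1. Genes with fewer than 10 total matches are
flagged and excluded from hit calling; the remainder are BH-FDR
corrected and thresholded at $10^{-4}$ by default. The comparison-wide
$M$ is the default; the binomial model treats matches as independent
across pairs, which is approximate because pairs sharing a neuron are
dependent — on neuron-level random expression the score shows a slight
excess in the extreme tail while remaining super-uniform above
$\alpha \approx 0.1$, one reason the stringent threshold and FDR step
matter. Over-representation of hit genes in annotation categories uses
the hypergeometric upper tail within the scored background, restricted
to categories with 5–100 background genes, BH-corrected across
categories (a generic ORA; no attempt to reproduce any specific ORA
tool's internals).

## Group comparisons and permutation nulls

Rank-sum comparisons wrap the Wilcoxon test (exact for small untied
samples, tie-corrected normal approximation otherwise); Welch's t-test
with Satterthwaite degrees of freedom is used for distance contrasts;
Spearman correlation with average ranks for lineage-distance analyses.
One-sided directions are always stated by the caller, never inferred
from the data. The composition-matched permutation null draws random
neuron sets matching the attribute composition of a target set (e.g.
thirteen cholinergic + two glutamatergic + one unknown, or thirteen
head + three tail neurons), computes each set's median pairwise CGE, and
reports an add-one permutation p-value. The default is $10^5$
permutations rather than the $10^8$ used in the original analyses: the
effect sizes of interest (p-values of order $3 \times 10^{-4}$ and
larger) are fully resolvable at $10^5$, at desk-scale runtime.

## The synthetic generator: what it emulates, and what it does not

`synth_config()` defaults define the study conditions: 147 head neurons
within 130 μm, 105 body neurons over 1.02 mm, 27 tail neurons within
90 μm; connection probability $A e^{-\lambda d} + B$ with
$A = 0.1$, $\lambda = 0.01\,\mu m^{-1}$, $B = 0.005$ (giving ~2,500
directed connections and a mean degree near the real network's ~21,
with a distinct high-degree tail); 16 planted hubs (command
interneurons first, then random head/tail neurons) reciprocally
connected at pair density 0.8; 20% of connected pairs stored as gap
junctions; 948 genes at baseline expression probability 0.05 with 20
genes planted at probability 0.9 in hubs; 92 bilateral pairs generated
as row copies with per-entry flip probability 0.005 (so homologs have
$r_\phi$ near 1, matching the observed homolog similarity, and are
exactly identical when the flip probability is 0); bimodal birth times
(< 550 or > 1200 min). A single global seed is expanded into
independent per-generator streams, so changing the gene count does not
perturb the connectome draw.

The generator reproduces the *statistical structure* the analysis
assumes — spatially clustered neurons, distance-decaying connectivity, a
planted rich club, sparse binary expression with hub-coupled genes and
near-identical homologs — but not the real organism: no real lineage
tree (lineage distances are small random integers), no real gene
identities, no anatomy-ontology structure, and annotation sparsity is
homogeneous rather than study-driven. Passing the planted-signal and
calibration tests therefore demonstrates that the statistics detect the
structure they target at realistic scale and are calibrated in its
absence; it does not validate any biological claim about real data.

On synthetic draws the real-data hub cutoff `k > 44` has no meaning, so
synthetic analyses define hubs as the sixteen highest-degree neurons
(threshold = 17th largest degree), mirroring the way the real cutoff was
chosen (the lowest threshold giving a contiguous significant rich-club
regime with sixteen hubs).

## Numerical and design choices

- Permutation and rank statistics never return p = 0 (add-one
  estimators; exact Wilcoxon enumeration where feasible).
- Equiprobable bin assignment is by sorted position, so duplicated
  distances (each unordered distance appears twice among ordered pairs)
  are split deterministically.
- Undefined similarities, medians over empty classes, and degenerate
  fits (constant data, < 4 points) are flagged (`NA`, warnings), not
  silently zeroed.
- Neuron identity is the trimmed, case-sensitive name string.
- Multi-label functional types are stored as semicolon lists;
  "connections involving type T" means at least one endpoint carries T.
- Whether multiple synapses between a pair contribute once or
  weight-times to degree is not documented for the binary network; the
  binarized convention (once per mechanism) is adopted and the weighted
  rich-club variant is the place where synapse counts matter.

## Problem sizes used by the shipped tests

The test suite exercises the full 279-neuron, 948-gene scale
throughout. Ensemble sizes are chosen for desk-scale runs: 150–500
rewiring nulls (the normalized curve stabilizes well below the 1000
used for publication-scale runs), 10 seeds for planted-signal recovery,
200 seeds for null calibration, $10^3$–$2 \times 10^4$ permutations for
the composition-matched nulls, and 10–200 Louvain repeats in consensus
clustering. All of these are parameters of the corresponding functions
and can be raised for publication-scale analyses.

## Known limitations

- The binomial gene score inherits the independence approximation
  discussed above; interpret near-threshold scores with the FDR step.
- Louvain consensus depends on the agreement threshold `tau` for
  poorly separated module structure; the consensus parameters of the
  reference analyses are not published, so defaults are exposed rather
  than asserted as ground truth.
- `p_match` is this package's construction of a
  probability-of-mutual-expression index, not a reproduction of any
  published formula.
- Real-data workflows require the published connectome/expression
  bundle as TSV inputs; no retrieval or ontology propagation is
  performed by this package.

## A worked example

```{r example, eval = FALSE}
library(nemacge)

ds <- simulate_dataset(synth_config(seed = 1))
deg <- degree_sequence(ds$connectome)
k_thr <- sort(deg$k, decreasing = TRUE)[17]

rc <- normalized_rich_club(ds$connectome, n_null = 500, seed = 1)
subset(rc, p_perm < 0.05 & phi_norm > 1)$k

bil <- bilateral_pairs(ds$neurons)
cge <- cge_matrix(ds$expression, "r_phi", bilateral_pairs = bil)
gs <- score_genes(ds$expression, ds$connectome,
                  "hub_involved_vs_peripheral", k_threshold = k_thr,
                  exclude_pairs = bil)
head(gs[order(gs$p_a), ])
```
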