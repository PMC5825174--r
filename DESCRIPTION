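Package: nemacge
Title: Hub Connectivity and Correlated Gene Expression in Neuronal Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links hub connectivity of a neuronal connectome to correlated
    binary gene expression. Implements the rich-club coefficient with
    degree-preserving rewiring nulls, a binary coexpression statistic (the
    mean square contingency coefficient) with bilateral-homolog exclusion,
    edge-class comparisons of correlated gene expression, permutation tests
    against composition-matched neuron sets, a binomial gene-contribution
    score with false discovery rate control, over-representation analysis,
    distance-dependent connection probability curves with exponential fits,
    and Louvain consensus modularity. A synthetic-data generator emulates
    the statistical structure of the C. elegans somatic connectome (279
    neurons in three spatial clusters, sparse binary expression across ~950
    genes, bilateral homolog pairs, and a planted rich club) so the full
    pipeline is testable end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
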