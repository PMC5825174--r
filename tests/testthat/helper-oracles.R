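# Independent brute-force oracles and small fixtures used across tests.
# These deliberately recompute quantities by direct enumeration, not via
# the package's own code paths.

# Brute-force rich-club coefficient: count, over all unordered node pairs,
# those connected in either direction among nodes with degree > k, where
# degree is the number of incident directed edges (gap junctions expanded).
oracle_phi <- function(cn, k) {
  de <- directed_edges(cn)
  nodes <- cn$neurons
  deg <- sapply(nodes, function(v) sum(de$pre == v) + sum(de$post == v))
  keep <- nodes[deg > k]
  if (length(keep) < 2) return(NA_real_)
  e <- 0
  for (i in seq_along(keep)) for (j in seq_along(keep)) {
    if (i < j) {
      a <- keep[i]; b <- keep[j]
      if (any(de$pre == a & de$post == b) || any(de$pre == b & de$post == a))
        e <- e + 1
    }
  }
  2 * e / (length(keep) * (length(keep) - 1))
}

# Elementwise recount of the four binary similarity measures.
oracle_similarity <- function(x, y, method) {
  n11 <- 0; n10 <- 0; n01 <- 0; n00 <- 0
  for (i in seq_along(x)) {
    if (x[i] == 1 && y[i] == 1) n11 <- n11 + 1
    else if (x[i] == 1) n10 <- n10 + 1
    else if (y[i] == 1) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  L <- length(x)
  if (method == "r_phi") {
    den <- (n11 + n10) * (n01 + n00) * (n10 + n00) * (n11 + n01)
    if (den == 0) return(NA_real_)
    return((n11 * n00 - n10 * n01) / sqrt(den))
  }
  if (method == "jaccard") {
    den <- n11 + n10 + n01
    return(if (den == 0) NA_real_ else n11 / den)
  }
  if (method == "yule_q") {
    den <- n11 * n00 + n10 * n01
    return(if (den == 0) NA_real_ else (n11 * n00 - n10 * n01) / den)
  }
  if (method == "p_match") {
    a <- n11 + n10; b <- n11 + n01
    if (a == 0 || b == 0) return(NA_real_)
    # exhaustive hypergeometric tail: place b ones among L slots, a fixed
    tail <- sum(sapply(n11:min(a, b), function(h)
      choose(a, h) * choose(L - a, b - h))) / choose(L, b)
    return(1 - tail)
  }
  stop("unknown method")
}

# Exhaustive binomial upper tail over the full outcome tree of n Bernoulli
# trials (feasible for n <= 12): P(at least m successes).
oracle_binom_tail <- function(m, n, p) {
  if (m == 0) return(1)
  if (n == 0) return(0)
  outcomes <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  sum(probs[rowSums(outcomes) >= m])
}

# Toy three-neuron connectome: chemical A->B, gap B-C.
toy_connectome <- function() {
  connectome(c("A", "B", "C"),
             chem = data.frame(pre = "A", post = "B", weight = 1),
             gap = data.frame(a = "B", b = "C", weight = 1))
}

# Random directed graph as a connectome (chemical edges only).
random_connectome <- function(n_nodes, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  adj <- matrix(runif(n_nodes^2) < p, n_nodes, n_nodes)
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  connectome(nodes, chem = data.frame(pre = nodes[idx[, 1]],
                                      post = nodes[idx[, 2]], weight = 1))
}

# Hub threshold used for synthetic analyses: the 17th largest degree, so
# that exactly the top 16 neurons are hubs (mirrors the real-data k > 44
# construction).
top16_threshold <- function(deg) sort(deg$k, decreasing = TRUE)[17]
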