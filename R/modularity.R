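# Louvain consensus partitioning and module-aware pair sets.

# Relabel a membership vector: ids contiguous from 1, size-descending,
# ties broken by smallest original id.
relabel_modules <- function(membership) {
  tab <- table(membership)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  map <- stats::setNames(seq_along(ord), names(tab)[ord])
  out <- as.integer(map[as.character(membership)])
  names(out) <- names(membership)
  out
}

# Symmetrized (OR) undirected simple graph of a connectome.
symmetrized_graph <- function(c) {
  pr <- connected_pairs(c)
  igraph::graph_from_data_frame(pr[, c("a", "b")], directed = FALSE,
                                vertices = data.frame(name = c$neurons))
}

#' Louvain consensus community detection
#'
#' Runs the Louvain algorithm `n_runs` times on the symmetrized (undirected)
#' connectome, builds an agreement matrix in which each run is weighted by
#' its modularity Q, zeroes entries below `tau`, and re-clusters the
#' agreement matrix iteratively until all runs agree on one partition.
#' Deterministic given the seed.
#'
#' @param c a [connectome()] with at least one edge.
#' @param n_runs Louvain repeats (>= 2; default 1000).
#' @param tau agreement threshold in \[0, 1\] (default 0.4).
#' @param seed integer seed.
#' @param max_consensus_iter safety cap on consensus iterations.
#' @return list of class `modular_partition`: `membership` (named integer
#'   vector, module ids contiguous from 1, size-descending), `Q`
#'   (modularity of the consensus partition on the symmetrized graph),
#'   `n_runs`, `source = "louvain_consensus"`, and `Q_runs`.
#' @export
louvain_consensus <- function(c, n_runs = 1000, tau = 0.4, seed = 1,
                              max_consensus_iter = 20) {
  if (n_runs < 2) stop_config("n_runs must be >= 2")
  g <- symmetrized_graph(c)
  if (igraph::ecount(g) < 1) stop_config("graph has no edges")
  nv <- igraph::vcount(g)

  run_batch <- function(graph, weights, label) {
    memb <- matrix(NA_integer_, nrow = n_runs, ncol = nv)
    q <- numeric(n_runs)
    for (i in seq_len(n_runs)) {
      cl <- with_seed(sub_seed(seed, paste0(label, i)),
                      igraph::cluster_louvain(graph, weights = weights))
      memb[i, ] <- igraph::membership(cl)
      q[i] <- max(igraph::modularity(cl))
    }
    list(memb = memb, q = q)
  }
  agreement <- function(memb, q) {
    w <- pmax(q, 0); if (sum(w) == 0) w <- rep(1, length(q))
    d <- matrix(0, nv, nv)
    for (i in seq_len(nrow(memb)))
      d <- d + w[i] * outer(memb[i, ], memb[i, ], `==`)
    d / sum(w)
  }

  b <- run_batch(g, weights = NULL, label = "lv")
  q_runs <- b$q
  for (iter in seq_len(max_consensus_iter)) {
    if (nrow(unique(b$memb)) == 1) break
    d <- agreement(b$memb, b$q)
    d[d < tau] <- 0
    diag(d) <- 0
    ag <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                              weighted = TRUE)
    igraph::V(ag)$name <- c$neurons
    b <- run_batch(ag, weights = igraph::E(ag)$weight,
                   label = paste0("cons", iter))
  }
  membership <- stats::setNames(b$memb[1, ], c$neurons)
  membership <- relabel_modules(membership)
  Q <- igraph::modularity(g, membership)
  structure(list(membership = membership, Q = Q, n_runs = n_runs,
                 source = "louvain_consensus", Q_runs = q_runs),
            class = "modular_partition")
}

#' @export
print.modular_partition <- function(x, ...) {
  cat(sprintf("modular partition (%s): %d modules, Q = %.3f\n",
              x$source, max(x$membership), x$Q))
  print(table(x$membership))
  invisible(x)
}

#' Load an externally derived partition
#'
#' TSV with columns `neuron` and `module`; every neuron of the connectome
#' must be assigned.
#'
#' @param tsv path to the partition file.
#' @param c a [connectome()] (defines the neuron universe), or a character
#'   vector of neurons.
#' @return a `modular_partition` with `source = "external"`.
#' @export
load_partition <- function(tsv, c) {
  neurons <- if (inherits(c, "connectome")) c$neurons else as.character(c)
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  if (!all(c("neuron", "module") %in% names(tab)))
    stop_data("partition file needs columns 'neuron' and 'module'")
  miss <- setdiff(neurons, tab$neuron)
  if (length(miss) > 0)
    stop_data("partition missing neuron '%s'", miss[1])
  membership <- stats::setNames(tab$module[match(neurons, tab$neuron)], neurons)
  membership <- relabel_modules(membership)
  structure(list(membership = membership, Q = NA_real_, n_runs = 0L,
                 source = "external", Q_runs = numeric()),
            class = "modular_partition")
}

#' Split connected pairs into intra- and inter-module sets
#'
#' @param c a [connectome()].
#' @param partition a `modular_partition`.
#' @param exclude_pairs optional two-column matrix of pairs to drop first
#'   (bilateral homologs).
#' @return list with two-column matrices `intra` and `inter`.
#' @export
module_pair_sets <- function(c, partition, exclude_pairs = NULL) {
  cp <- connected_pairs(c)
  if (!is.null(exclude_pairs) && nrow(exclude_pairs) > 0) {
    drop <- pair_key(cp$a, cp$b) %in%
      pair_key(exclude_pairs[, 1], exclude_pairs[, 2])
    cp <- cp[!drop, , drop = FALSE]
  }
  m <- partition$membership
  same <- m[cp$a] == m[cp$b]
  list(intra = cbind(a = cp$a[same], b = cp$b[same]),
       inter = cbind(a = cp$a[!same], b = cp$b[!same]))
}
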