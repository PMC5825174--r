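# Rich-club organization: phi(k), degree-preserving rewiring nulls,
# normalized curve with permutation p-values, weighted variants, and
# hub-distance statistics.

# Internal: phi(k) for a whole k-range at once.
# deg: named integer vector of total degrees (per the mechanism-summed
# convention); pairs: data.frame a/b of connected unordered pairs;
# dir_pairs: 2-col matrix of unique directed edges (for the directed mode).
phi_curve_internal <- function(deg, pairs, dir_pairs, ks,
                               edge_count = c("pairs", "directed")) {
  edge_count <- match.arg(edge_count)
  n_gt <- vapply(ks, function(k) sum(deg > k), integer(1))
  if (edge_count == "pairs") {
    mind <- pmin(deg[pairs$a], deg[pairs$b])
    e_gt <- vapply(ks, function(k) sum(mind > k), integer(1))
    phi <- ifelse(n_gt >= 2, 2 * e_gt / (n_gt * (n_gt - 1)), NA_real_)
  } else {
    mind <- pmin(deg[dir_pairs[, 1]], deg[dir_pairs[, 2]])
    e_gt <- vapply(ks, function(k) sum(mind > k), integer(1))
    phi <- ifelse(n_gt >= 2, e_gt / (n_gt * (n_gt - 1)), NA_real_)
  }
  list(n_gt = n_gt, e_gt = e_gt, phi = phi)
}

#' Rich-club coefficient at a single degree threshold
#'
#' phi(k) = 2 E_{>k} / (N_{>k} (N_{>k} - 1)), where N_{>k} is the number of
#' neurons with total degree > k and E_{>k} counts connected unordered pairs
#' among them (so that phi is a link density in \[0, 1\]). An alternative
#' directed-edge density E / (N (N - 1)) is available via `edge_count`.
#'
#' @param c a [connectome()].
#' @param k non-negative degree threshold.
#' @param edge_count `"pairs"` (default) or `"directed"`.
#' @return phi(k), or `NA` (flagged undefined) when fewer than two neurons
#'   exceed the threshold.
#' @export
rich_club_phi <- function(c, k, edge_count = c("pairs", "directed")) {
  if (!is.numeric(k) || length(k) != 1 || k < 0)
    stop_config("k must be a single non-negative number")
  edge_count <- match.arg(edge_count)
  deg <- degree_sequence(c)
  degv <- stats::setNames(deg$k, deg$neuron)
  pr <- connected_pairs(c)
  de <- directed_edges(c)
  dp <- unique(cbind(de$pre, de$post))
  phi_curve_internal(degv, pr, dp, k, edge_count)$phi
}

#' Degree-preserving rewiring null
#'
#' Randomizes the combined directed network by double-edge swaps
#' (Maslov-Sneppen rewiring, as in the Brain Connectivity Toolbox's
#' `randmio_dir`) that forbid self-edges and duplicate directed edges, so the
#' in- and out-degree sequences and the edge count are preserved exactly.
#' Gap junctions enter as two directed edges swapped independently unless
#' `preserve_gap_reciprocity` is set, in which case gap junctions are
#' rewired among themselves as undirected swaps.
#'
#' @param c a [connectome()] with at least 2 directed edges.
#' @param iters_per_edge average number of times each edge is rewired.
#' @param seed integer seed (mandatory; the null is deterministic given it).
#' @param preserve_gap_reciprocity logical.
#' @return a [connectome()] holding the rewired directed network (mechanism
#'   identity of rewired edges is not meaningful). Attribute `n_changed`
#'   counts edges whose endpoints differ from the input.
#' @export
rewire_null <- function(c, iters_per_edge = 50, seed,
                        preserve_gap_reciprocity = FALSE) {
  stopifnot(inherits(c, "connectome"))
  de <- directed_edges(c)
  if (nrow(de) < 2) stop_config("need at least 2 directed edges to rewire")
  idx <- match(c(de$pre, de$post), c$neurons)
  rewire_one <- function(edge_df, directed) {
    g <- igraph::graph_from_data_frame(edge_df[, c("pre", "post")],
                                       directed = directed,
                                       vertices = data.frame(name = c$neurons))
    niter <- max(1L, ceiling(iters_per_edge * nrow(edge_df)))
    g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
    el <- igraph::as_data_frame(g2, what = "edges")
    # rewiring drops attributes; weights are reattached in edge order (any
    # weighted analysis of a null permutes them anyway)
    data.frame(pre = el$from, post = el$to, weight = edge_df$weight,
               stringsAsFactors = FALSE)
  }
  out <- with_seed(seed, {
    if (preserve_gap_reciprocity) {
      chem <- c$chem
      gap <- c$gap
      new_chem <- if (nrow(chem) >= 2)
        rewire_one(data.frame(pre = chem$pre, post = chem$post,
                              weight = chem$weight), directed = TRUE) else chem
      new_gap <- if (nrow(gap) >= 2) {
        gg <- rewire_one(data.frame(pre = gap$a, post = gap$b,
                                    weight = gap$weight), directed = FALSE)
        data.frame(a = gg$pre, b = gg$post, weight = gg$weight,
                   stringsAsFactors = FALSE)
      } else gap
      connectome(c$neurons, chem = new_chem, gap = new_gap,
                 neuron_table = c$neuron_table)
    } else {
      el <- rewire_one(de, directed = TRUE)
      # collapse any residual duplicated directed records by summing weights
      key <- paste(el$pre, el$post)
      if (anyDuplicated(key)) {
        w <- tapply(el$weight, key, sum)
        parts <- strsplit(names(w), " ", fixed = TRUE)
        el <- data.frame(pre = vapply(parts, `[`, "", 1),
                         post = vapply(parts, `[`, "", 2),
                         weight = as.numeric(w), stringsAsFactors = FALSE)
      }
      connectome(c$neurons, chem = el, neuron_table = c$neuron_table)
    }
  })
  before <- sort(paste(de$pre, de$post))
  after <- sort(paste(directed_edges(out)$pre, directed_edges(out)$post))
  n_changed <- sum(before != after)
  if (n_changed == 0 && nrow(de) >= 2)
    warning("no effective swaps: graph too small or rigid to rewire")
  attr(out, "n_changed") <- n_changed
  out
}

# Internal: distance statistics for rich pairs at each k.
hub_distance_stats <- function(degv, pairs, pos, ks) {
  md <- rep(NA_real_, length(ks)); pd <- rep(NA_real_, length(ks))
  if (is.null(pos)) return(list(mean_hub_distance = md, p_distance = pd))
  d <- sqrt((pos[pairs$a, 1] - pos[pairs$b, 1])^2 +
            (pos[pairs$a, 2] - pos[pairs$b, 2])^2)
  mind <- pmin(degv[pairs$a], degv[pairs$b])
  for (i in seq_along(ks)) {
    rich <- mind > ks[i]
    if (sum(rich) >= 2 && sum(!rich) >= 2) {
      md[i] <- mean(d[rich])
      if (stats::sd(d[rich]) > 0 || stats::sd(d[!rich]) > 0)
        pd[i] <- tryCatch(
          stats::t.test(d[rich], d[!rich], alternative = "greater")$p.value,
          error = function(e) NA_real_)
    } else if (sum(rich) >= 1) md[i] <- mean(d[rich])
  }
  list(mean_hub_distance = md, p_distance = pd)
}

# Internal: neuron positions as a 2-col matrix with neuron rownames, or NULL.
neuron_positions <- function(c) {
  nt <- c$neuron_table
  if (is.null(nt) || !all(c("x_um", "y_um") %in% names(nt))) return(NULL)
  pos <- as.matrix(nt[, c("x_um", "y_um")])
  rownames(pos) <- nt$neuron
  pos[c$neurons, , drop = FALSE]
}

#' Normalized rich-club curve with permutation p-values
#'
#' Computes phi(k) for every threshold, the mean phi over an ensemble of
#' degree-preserving rewiring nulls, their ratio Phi_norm(k), and a
#' permutation p-value per k using the add-one estimator
#' p = (1 + #\{phi_rand >= phi\}) / (n_null + 1). When neuron positions are
#' available, the mean Euclidean distance over connected hub pairs and a
#' right-tailed Welch t-test against all other connected pairs are added.
#'
#' @param c a [connectome()].
#' @param n_null number of null networks (>= 1).
#' @param iters_per_edge rewiring intensity per null.
#' @param seed integer seed.
#' @param edge_count `"pairs"` or `"directed"` (see [rich_club_phi()]).
#' @param k_range integer thresholds; default 0 to max(k) - 1.
#' @param preserve_gap_reciprocity passed to [rewire_null()].
#' @return data.frame of class `rich_club_curve` with columns `k`, `N_gt`,
#'   `E_gt`, `phi`, `phi_rand_mean`, `phi_norm`, `p_perm`,
#'   `mean_hub_distance`, `p_distance`.
#' @export
normalized_rich_club <- function(c, n_null = 1000, iters_per_edge = 50, seed,
                                 edge_count = c("pairs", "directed"),
                                 k_range = NULL,
                                 preserve_gap_reciprocity = FALSE) {
  if (n_null < 1) stop_config("n_null must be >= 1")
  edge_count <- match.arg(edge_count)
  deg <- degree_sequence(c)
  degv <- stats::setNames(deg$k, deg$neuron)
  if (is.null(k_range)) k_range <- 0:(max(degv) - 1)
  pr <- connected_pairs(c)
  de <- directed_edges(c)
  emp <- phi_curve_internal(degv, pr, unique(cbind(de$pre, de$post)),
                            k_range, edge_count)
  null_phi <- matrix(NA_real_, nrow = n_null, ncol = length(k_range))
  for (i in seq_len(n_null)) {
    nl <- suppressWarnings(
      rewire_null(c, iters_per_edge, seed = sub_seed(seed, paste0("null", i)),
                  preserve_gap_reciprocity = preserve_gap_reciprocity))
    npr <- connected_pairs(nl)
    nde <- directed_edges(nl)
    ndeg <- degree_sequence(nl)
    ndegv <- stats::setNames(ndeg$k, ndeg$neuron)
    null_phi[i, ] <- phi_curve_internal(ndegv, npr,
                                        unique(cbind(nde$pre, nde$post)),
                                        k_range, edge_count)$phi
  }
  phi_rand_mean <- colMeans(null_phi)
  phi_norm <- emp$phi / phi_rand_mean
  p_perm <- vapply(seq_along(k_range), function(j) {
    if (is.na(emp$phi[j])) return(NA_real_)
    perm_p(sum(null_phi[, j] >= emp$phi[j], na.rm = TRUE), n_null)
  }, numeric(1))
  dstat <- hub_distance_stats(degv, pr, neuron_positions(c), k_range)
  out <- data.frame(k = k_range, N_gt = emp$n_gt, E_gt = emp$e_gt,
                    phi = emp$phi, phi_rand_mean = phi_rand_mean,
                    phi_norm = phi_norm, p_perm = p_perm,
                    mean_hub_distance = dstat$mean_hub_distance,
                    p_distance = dstat$p_distance)
  class(out) <- c("rich_club_curve", "data.frame")
  out
}

#' Weighted rich-club curve
#'
#' The weighted coefficient at threshold k is the total weight of directed
#' connections among neurons with degree > k divided by the sum of the
#' equally many largest weights anywhere in the network. Two null models
#' are available: `weight_shuffle` permutes weights over the fixed edge set
#' (topology fixed); `topology_and_weights` applies degree-preserving
#' rewiring and then permutes weights.
#'
#' @param c a [connectome()] with weights.
#' @param null_type `"weight_shuffle"` or `"topology_and_weights"`.
#' @param n_null ensemble size.
#' @param iters_per_edge rewiring intensity (second null type only).
#' @param seed integer seed.
#' @param k_range integer thresholds; default 0 to max(k) - 1.
#' @return data.frame with columns `k`, `N_gt`, `E_gt`, `phi_w`,
#'   `phi_rand_mean`, `phi_norm`, `p_perm`.
#' @export
weighted_rich_club <- function(c, null_type = c("weight_shuffle",
                                                "topology_and_weights"),
                               n_null = 1000, iters_per_edge = 50, seed,
                               k_range = NULL) {
  null_type <- match.arg(null_type)
  deg <- degree_sequence(c)
  degv <- stats::setNames(deg$k, deg$neuron)
  if (is.null(k_range)) k_range <- 0:(max(degv) - 1)

  phiw <- function(degv_loc, de) {
    w_sorted <- sort(de$weight, decreasing = TRUE)
    cw <- cumsum(w_sorted)
    mind <- pmin(degv_loc[de$pre], degv_loc[de$post])
    vapply(k_range, function(k) {
      n_gt <- sum(degv_loc > k)
      if (n_gt < 2) return(NA_real_)
      sel <- mind > k
      e <- sum(sel)
      if (e == 0) return(0)
      sum(de$weight[sel]) / cw[e]
    }, numeric(1))
  }

  de <- directed_edges(c)
  emp <- phiw(degv, de)
  null_mat <- matrix(NA_real_, nrow = n_null, ncol = length(k_range))
  for (i in seq_len(n_null)) {
    s <- sub_seed(seed, paste0("wnull", i))
    if (null_type == "weight_shuffle") {
      de_i <- de
      de_i$weight <- with_seed(s, sample(de$weight))
      null_mat[i, ] <- phiw(degv, de_i)
    } else {
      nl <- suppressWarnings(rewire_null(c, iters_per_edge, seed = s))
      nde <- directed_edges(nl)
      nde$weight <- with_seed(sub_seed(s, "w"), sample(nde$weight))
      ndeg <- degree_sequence(nl)
      null_mat[i, ] <- phiw(stats::setNames(ndeg$k, ndeg$neuron), nde)
    }
  }
  phi_rand_mean <- colMeans(null_mat)
  n_gt <- vapply(k_range, function(k) sum(degv > k), integer(1))
  mind <- pmin(degv[de$pre], degv[de$post])
  e_gt <- vapply(k_range, function(k) sum(mind > k), integer(1))
  p_perm <- vapply(seq_along(k_range), function(j) {
    if (is.na(emp[j])) return(NA_real_)
    perm_p(sum(null_mat[, j] >= emp[j], na.rm = TRUE), n_null)
  }, numeric(1))
  data.frame(k = k_range, N_gt = n_gt, E_gt = e_gt, phi_w = emp,
             phi_rand_mean = phi_rand_mean, phi_norm = emp / phi_rand_mean,
             p_perm = p_perm)
}
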