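# Per-gene contribution scoring: match counts over edge classes, the
# binomial tail score, FDR correction, and over-representation analysis.

#' All unordered neuron pairs, with exclusions
#'
#' @param neurons character vector of neuron names.
#' @param exclude two-column matrix of pairs to drop (e.g. bilateral
#'   homologs), or `NULL`.
#' @return two-column character matrix of unordered pairs.
#' @export
neuron_pair_universe <- function(neurons, exclude = NULL) {
  idx <- utils::combn(length(neurons), 2)
  pairs <- cbind(a = neurons[idx[1, ]], b = neurons[idx[2, ]])
  if (!is.null(exclude) && nrow(exclude) > 0) {
    drop <- pair_key(pairs[, 1], pairs[, 2]) %in%
      pair_key(exclude[, 1], exclude[, 2])
    pairs <- pairs[!drop, , drop = FALSE]
  }
  pairs
}

#' Per-gene match counts over two pair classes
#'
#' A match for gene a on a pair means the gene is expressed in both
#' neurons. `m` counts matches on the class of interest, `n` matches over
#' class and alternative together, `M` the number of pairs considered, and
#' `n_class` the number of class pairs.
#'
#' @param e binary neurons x genes matrix.
#' @param class_pairs,alternative_pairs disjoint two-column matrices of
#'   unordered neuron pairs (bilateral pairs pre-excluded).
#' @return data.frame `gene`, `m`, `n`, `M`, `n_class`.
#' @export
edge_match_counts <- function(e, class_pairs, alternative_pairs) {
  ck <- pair_key(class_pairs[, 1], class_pairs[, 2])
  ak <- pair_key(alternative_pairs[, 1], alternative_pairs[, 2])
  if (length(intersect(ck, ak)) > 0)
    stop_config("class and alternative pair sets overlap")
  match_counts <- function(pairs) {
    if (nrow(pairs) == 0) return(rep(0L, ncol(e)))
    as.integer(colSums(e[pairs[, 1], , drop = FALSE] *
                       e[pairs[, 2], , drop = FALSE]))
  }
  m <- match_counts(class_pairs)
  n <- m + match_counts(alternative_pairs)
  data.frame(gene = colnames(e), m = m, n = n,
             M = nrow(class_pairs) + nrow(alternative_pairs),
             n_class = nrow(class_pairs), stringsAsFactors = FALSE)
}

#' Binomial upper-tail gene score
#'
#' The probability of observing at least `m` matches on the class of
#' interest out of `n` total matches when each match falls on the class
#' independently with probability `p_class`: P(X >= m), X ~
#' Binomial(n, p_class). Computed with the survival function (numerically
#' stable for small tails); `m = 0` gives exactly 1.
#'
#' @param m,n match counts (vectors allowed), `0 <= m <= n`.
#' @param p_class class probability in (0, 1).
#' @return upper-tail probabilities.
#' @export
binomial_score <- function(m, n, p_class) {
  if (any(p_class <= 0 | p_class >= 1))
    stop_config("p_class must lie strictly inside (0, 1)")
  if (any(m < 0 | m > n)) stop_config("need 0 <= m <= n")
  stats::pbinom(m - 1, n, p_class, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted values (step-up with monotonicity enforcement).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_data("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Score every gene's contribution to a CGE contrast
#'
#' Two comparisons are supported. `connected_vs_unconnected` contrasts
#' pairs of neurons connected by at least one synapse against unconnected
#' pairs; `hub_involved_vs_peripheral` contrasts connected pairs involving
#' at least one hub (rich, feed-in or feed-out) against connected pairs of
#' nonhubs (peripheral). Bilateral homolog pairs are excluded throughout.
#' `p_class` is recomputed from the actual pair universe as
#' n_class / M. Genes with n < `min_n` are flagged and excluded from hit
#' calling and FDR; hits are genes with FDR-adjusted score below `alpha`.
#'
#' @param e binary neurons x genes matrix (rownames = neurons of `c`).
#' @param c a [connectome()].
#' @param comparison `"connected_vs_unconnected"` or
#'   `"hub_involved_vs_peripheral"`.
#' @param k_threshold hub degree threshold (default 44).
#' @param min_n data-quality threshold on total matches (default 10).
#' @param alpha hit threshold on the FDR-adjusted score (default 1e-4).
#' @param exclude_pairs two-column matrix of pairs to exclude (bilateral
#'   homologs).
#' @return data.frame of class `gene_score_table`: `gene`, `m`, `n`, `M`,
#'   `n_class`, `p_class`, `p_a`, `p_corr`, `passes_min_n`, `hit`;
#'   attribute `p_class` repeats the class probability.
#' @export
score_genes <- function(e, c,
                        comparison = c("connected_vs_unconnected",
                                       "hub_involved_vs_peripheral"),
                        k_threshold = 44, min_n = 10, alpha = 1e-4,
                        exclude_pairs = NULL) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(c, "connectome"))
  if (!all(rownames(e) %in% c$neurons))
    stop_data("expression matrix and connectome neuron universes differ")
  cp <- connected_pairs(c)
  ckey <- pair_key(cp$a, cp$b)
  if (!is.null(exclude_pairs) && nrow(exclude_pairs) > 0) {
    xkey <- pair_key(exclude_pairs[, 1], exclude_pairs[, 2])
    cp <- cp[!ckey %in% xkey, , drop = FALSE]
    ckey <- pair_key(cp$a, cp$b)
  }
  if (comparison == "connected_vs_unconnected") {
    universe <- neuron_pair_universe(rownames(e), exclude = exclude_pairs)
    is_class <- pair_key(universe[, 1], universe[, 2]) %in% ckey
    class_pairs <- universe[is_class, , drop = FALSE]
    alt_pairs <- universe[!is_class, , drop = FALSE]
  } else {
    hubs <- label_hubs(degree_sequence(c), k_threshold)
    is_hub <- stats::setNames(hubs$is_hub, hubs$neuron)
    involved <- is_hub[cp$a] | is_hub[cp$b]
    class_pairs <- cbind(a = cp$a[involved], b = cp$b[involved])
    alt_pairs <- cbind(a = cp$a[!involved], b = cp$b[!involved])
  }
  if (nrow(class_pairs) == 0) stop_data("empty class of neuron pairs")
  counts <- edge_match_counts(e, class_pairs, alt_pairs)
  p_class <- counts$n_class[1] / counts$M[1]
  counts$p_class <- p_class
  counts$p_a <- binomial_score(counts$m, counts$n, p_class)
  counts$passes_min_n <- counts$n >= min_n
  counts$p_corr <- NA_real_
  counts$p_corr[counts$passes_min_n] <- bh_fdr(counts$p_a[counts$passes_min_n])
  counts$hit <- counts$passes_min_n & !is.na(counts$p_corr) &
    counts$p_corr < alpha
  attr(counts, "p_class") <- p_class
  class(counts) <- c("gene_score_table", "data.frame")
  counts
}

#' Over-representation analysis of a hit gene list
#'
#' Hypergeometric upper-tail test of the overlap between the hits and each
#' annotation category (counted within the background), with BH-FDR across
#' categories. Categories with fewer than `min_size` or more than
#' `max_size` background genes are excluded.
#'
#' @param hits character vector of hit genes (subset of `background`).
#' @param background character vector of background genes.
#' @param annotations data.frame with columns `gene`, `category_id`,
#'   `category_name`.
#' @param min_size,max_size category size bounds (defaults 5 and 100).
#' @return data.frame `category_id`, `category_name`, `size`, `overlap`,
#'   `p`, `p_fdr`, sorted by p.
#' @export
ora <- function(hits, background, annotations, min_size = 5, max_size = 100) {
  if (!all(hits %in% background))
    stop_config("hits must be a subset of the background")
  if (nrow(annotations) == 0) {
    warning("empty annotation table")
    return(data.frame(category_id = character(), category_name = character(),
                      size = integer(), overlap = integer(), p = numeric(),
                      p_fdr = numeric(), stringsAsFactors = FALSE))
  }
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  split_genes <- split(ann$gene, ann$category_id)
  names_map <- tapply(ann$category_name, ann$category_id, `[`, 1)
  size <- vapply(split_genes, function(g) length(unique(g)), integer(1))
  keep <- size >= min_size & size <= max_size
  split_genes <- split_genes[keep]; size <- size[keep]
  if (length(split_genes) == 0) {
    warning("no categories within the size bounds")
    return(data.frame(category_id = character(), category_name = character(),
                      size = integer(), overlap = integer(), p = numeric(),
                      p_fdr = numeric(), stringsAsFactors = FALSE))
  }
  nb <- length(unique(background)); nh <- length(unique(hits))
  overlap <- vapply(split_genes,
                    function(g) length(intersect(unique(g), hits)), integer(1))
  p <- stats::phyper(overlap - 1, size, nb - size, nh, lower.tail = FALSE)
  out <- data.frame(category_id = names(split_genes),
                    category_name = as.character(names_map[names(split_genes)]),
                    size = size, overlap = overlap, p = p, p_fdr = bh_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), , drop = FALSE]
}
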