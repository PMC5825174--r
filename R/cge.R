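# Binary expression similarity: contingency counts, the phi coefficient and
# alternatives, the pairwise CGE matrix with exclusion masks, and the
# annotation-density bias simulation.

#' Read a binary expression table
#'
#' Long format TSV with columns `neuron`, `gene` and optionally `evidence`.
#' A 1 in the resulting matrix means the gene is annotated as expressed in
#' the neuron; a 0 means either "not expressed" or "no information". When an
#' `evidence` column is present, rows marked `uncertain` are dropped unless
#' `keep_uncertain` is set.
#'
#' @param path long-format TSV path.
#' @param neurons neuron universe (rows of the matrix); defaults to the
#'   neurons present in the file.
#' @param keep_uncertain logical.
#' @return binary matrix, neurons x genes.
#' @export
read_expression <- function(path, neurons = NULL, keep_uncertain = FALSE) {
  if (!file.exists(path)) stop_data("expression file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("neuron", "gene") %in% names(tab)))
    stop_data("expression table needs columns 'neuron' and 'gene'")
  if ("evidence" %in% names(tab) && !keep_uncertain)
    tab <- tab[tolower(tab$evidence) != "uncertain", , drop = FALSE]
  if (is.null(neurons)) neurons <- sort(unique(tab$neuron))
  bad <- setdiff(unique(tab$neuron), neurons)
  if (length(bad) > 0)
    stop_data("expression table references unknown neuron '%s'", bad[1])
  genes <- sort(unique(tab$gene))
  m <- matrix(0L, nrow = length(neurons), ncol = length(genes),
              dimnames = list(neurons, genes))
  m[cbind(match(tab$neuron, neurons), match(tab$gene, genes))] <- 1L
  m
}

#' Contingency counts for two binary vectors
#'
#' @param x,y binary vectors of equal length.
#' @return list with `n11`, `n10`, `n01`, `n00`, `L` and the four marginals
#'   `n1_`, `n0_`, `_1`, `_0` (row then column).
#' @export
contingency <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop_data("inputs must be binary (0/1)")
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  list(n11 = n11, n10 = n10, n01 = n01, n00 = n00, L = length(x),
       n1_ = n11 + n10, n0_ = n01 + n00, `_1` = n11 + n01, `_0` = n10 + n00)
}

# Internal scalar similarity from the four counts.
similarity_from_counts <- function(n11, n10, n01, n00, method) {
  L <- n11 + n10 + n01 + n00
  switch(method,
    r_phi = {
      den <- (n11 + n10) * (n01 + n00) * (n10 + n00) * (n11 + n01)
      ifelse(den > 0, (n11 * n00 - n10 * n01) / sqrt(den), NA_real_)
    },
    jaccard = {
      den <- n11 + n10 + n01
      ifelse(den > 0, n11 / den, NA_real_)
    },
    yule_q = {
      den <- n11 * n00 + n10 * n01
      ifelse(den > 0, (n11 * n00 - n10 * n01) / den, NA_real_)
    },
    p_match = {
      # probability-of-mutual-expression index: upper tail of the
      # fixed-marginals hypergeometric for >= n11 co-expressions, oriented
      # so larger = more coupled
      a <- n11 + n10; b <- n11 + n01
      tail <- stats::phyper(n11 - 1, a, L - a, b, lower.tail = FALSE)
      ifelse(a > 0 & b > 0, 1 - tail, NA_real_)
    },
    stop_config("unknown similarity method '%s'", method))
}

#' Similarity of two binary vectors from contingency counts
#'
#' Methods: `r_phi`, the mean square contingency (phi) coefficient
#' (n11 n00 - n10 n01) / sqrt(n1. n0. n.0 n.1) in \[-1, 1\]; `jaccard`,
#' n11 / (n11 + n10 + n01); `yule_q`; and `p_match`, one minus the
#' fixed-marginals hypergeometric upper-tail probability of observing at
#' least n11 co-expressions (a probability-of-mutual-expression index,
#' oriented so that larger values mean more coupled expression). A zero
#' marginal yields `NA` (flagged undefined, never coerced to 0).
#'
#' @param counts output of [contingency()].
#' @param method one of `"r_phi"`, `"jaccard"`, `"yule_q"`, `"p_match"`.
#' @return similarity value or `NA` when undefined.
#' @export
similarity <- function(counts, method = c("r_phi", "jaccard", "yule_q",
                                          "p_match")) {
  method <- match.arg(method)
  with(counts, similarity_from_counts(n11, n10, n01, n00, method))
}

#' Pairwise correlated gene expression (CGE) matrix
#'
#' Scores every unordered neuron pair with the requested similarity method.
#' Self-pairs and bilateral homolog pairs are masked with `NA` (left/right
#' mirror pairs have near-identical expression that would otherwise
#' dominate group statistics). Undefined similarities (zero marginal) are
#' also `NA`; the mask reason is recoverable from attribute `mask`.
#'
#' @param e binary neurons x genes matrix with rownames.
#' @param method similarity method (see [similarity()]).
#' @param bilateral_pairs two-column matrix/data.frame of neuron name pairs
#'   to mask, or `NULL`.
#' @param mask_bilateral set `FALSE` to score bilateral pairs (inspection).
#' @return symmetric matrix of class `cge_matrix` with `NA` diagonal;
#'   attributes `method` and `mask` (character matrix of reason codes:
#'   `"self"`, `"bilateral"`, `"undefined"` or `""`).
#' @export
cge_matrix <- function(e, method = c("r_phi", "jaccard", "yule_q", "p_match"),
                       bilateral_pairs = NULL, mask_bilateral = TRUE) {
  method <- match.arg(method)
  if (is.null(rownames(e))) stop_data("expression matrix needs neuron rownames")
  if (!all(e %in% c(0, 1))) stop_data("expression matrix must be binary")
  storage.mode(e) <- "double"
  n <- nrow(e); L <- ncol(e)
  n11 <- e %*% t(e)
  r1 <- rowSums(e)
  n10 <- outer(r1, rep(1, n)) - n11
  n01 <- t(n10)
  n00 <- L - n11 - n10 - n01
  s <- similarity_from_counts(n11, n10, n01, n00, method)
  mask <- matrix("", n, n, dimnames = dimnames(s))
  mask[is.na(s)] <- "undefined"
  diag(s) <- NA_real_
  diag(mask) <- "self"
  if (!is.null(bilateral_pairs) && nrow(bilateral_pairs) > 0 && mask_bilateral) {
    bp <- as.matrix(bilateral_pairs)
    bad <- setdiff(unique(as.vector(bp)), rownames(e))
    if (length(bad) > 0)
      stop_data("bilateral pair references unknown neuron '%s'", bad[1])
    i <- match(bp[, 1], rownames(e)); j <- match(bp[, 2], rownames(e))
    s[cbind(i, j)] <- NA_real_; s[cbind(j, i)] <- NA_real_
    mask[cbind(i, j)] <- "bilateral"; mask[cbind(j, i)] <- "bilateral"
  }
  attr(s, "method") <- method
  attr(s, "mask") <- mask
  class(s) <- c("cge_matrix", class(s))
  s
}

# Internal: CGE values for a set of unordered pairs given as name vectors.
cge_values <- function(cge, a, b) cge[cbind(a, b)]

#' Annotation-density bias of binary similarity measures
#'
#' Simulates, for every cell of a density grid, `n_pairs` independent pairs
#' of random binary vectors of length `L` whose only structure is their
#' proportion of ones, and reports the mean similarity per cell and method.
#' Under independence the overlap count is hypergeometric given the two
#' fixed annotation counts, which the simulation draws directly. An
#' unbiased measure has mean ~0 (r_phi) or no systematic trend across the
#' grid; density-biased measures (Jaccard, Yule's Q) show a strong trend.
#'
#' @param L vector length (genes).
#' @param density_grid proportions of ones to cross.
#' @param n_pairs pairs per cell.
#' @param methods character vector of similarity methods.
#' @param seed integer seed.
#' @return data.frame with `density_a`, `density_b`, `method`,
#'   `mean_value`, `n_pairs`.
#' @export
bias_simulation <- function(L = 948, density_grid = seq(0.01, 0.15, by = 0.02),
                            n_pairs = 1000,
                            methods = c("r_phi", "jaccard", "yule_q", "p_match"),
                            seed = 1) {
  if (any(density_grid < 0 | density_grid > 1))
    stop_config("densities must lie in [0, 1]")
  grid <- expand.grid(density_a = density_grid, density_b = density_grid)
  out <- list()
  for (m in methods) {
    vals <- vapply(seq_len(nrow(grid)), function(g) {
      a <- round(grid$density_a[g] * L)
      b <- round(grid$density_b[g] * L)
      h <- with_seed(sub_seed(seed, sprintf("bias-%s-%d", m, g)),
                     stats::rhyper(n_pairs, a, L - a, b))
      mean(similarity_from_counts(h, a - h, b - h, L - a - b + h, m))
    }, numeric(1))
    out[[m]] <- data.frame(grid, method = m, mean_value = vals,
                           n_pairs = n_pairs, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a CGE matrix as TSV (masked entries as NA)
#'
#' @param cge a [cge_matrix()].
#' @param path output path.
#' @export
write_cge <- function(cge, path) {
  utils::write.table(as.data.frame(unclass(cge)), path, sep = "\t",
                     quote = FALSE, na = "NA", col.names = NA)
  invisible(path)
}
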