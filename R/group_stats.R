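# Pairwise group comparisons and permutation nulls: edge-class CGE curves,
# driver analyses, and composition-matched neuron-set nulls.

comparison_result <- function(test, statistic, p, alternative,
                              median_a = NA, median_b = NA,
                              n_a = NA, n_b = NA) {
  structure(list(test = test, statistic = unname(statistic), p = unname(p),
                 alternative = alternative, median_a = median_a,
                 median_b = median_b, n_a = n_a, n_b = n_b),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, p = %.3g\n", x$test, x$alternative,
              x$statistic, x$p))
  cat(sprintf("  medians %.4g vs %.4g (n = %d, %d)\n",
              x$median_a, x$median_b, x$n_a, x$n_b))
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Exact p-value for small untied samples (both groups of size <= 50 and no
#' ties), tie-corrected normal approximation otherwise. `alternative =
#' "greater"` tests whether `a` is stochastically greater than `b`.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return a `comparison_result`.
#' @export
ranksum <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop_config("empty group")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = NULL, correct = TRUE))
  comparison_result("ranksum", wt$statistic, wt$p.value, alternative,
                    stats::median(a), stats::median(b), length(a), length(b))
}

#' Welch two-sample t-test
#'
#' @param a,b numeric samples with at least 2 values each.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return a `comparison_result`; statistic and p are `NA` (flagged
#'   undefined) when both groups have zero variance.
#' @export
welch_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop_config("need >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(comparison_result("welch", NA_real_, NA_real_, alternative,
                             stats::median(a), stats::median(b),
                             length(a), length(b)))
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  comparison_result("welch", tt$statistic, tt$p.value, alternative,
                    stats::median(a), stats::median(b), length(a), length(b))
}

#' Spearman rank correlation
#'
#' Average ranks for ties; constant input gives a flagged-undefined result.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a `comparison_result` with the correlation as `statistic`.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3)
    stop_config("need equal-length vectors with >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(comparison_result("spearman", NA_real_, NA_real_, "two.sided",
                             n_a = length(x), n_b = length(y)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  comparison_result("spearman", ct$estimate, ct$p.value, "two.sided",
                    n_a = length(x), n_b = length(y))
}

#' Median CGE per connection class across hub thresholds
#'
#' For each degree threshold k, directed connections are classified as
#' rich, feed-in, feed-out or peripheral, each connection takes the CGE of
#' its unordered neuron pair, and the per-class median over unmasked values
#' is reported together with a one-sided rank-sum test of the class against
#' the rest of the connected network (or against all pairs when
#' `scope = "all"`), flagged at p < 0.05.
#'
#' @param cge a [cge_matrix()].
#' @param c a [connectome()] over the same neurons.
#' @param k_range integer vector of thresholds.
#' @param scope `"connected"` (default) compares a class against all other
#'   connections; `"all"` against all other scored pairs.
#' @return data.frame `k`, `class`, `median_cge`, `n`, `p`, `flag`.
#' @export
edge_class_cge_curve <- function(cge, c, k_range, scope = c("connected", "all")) {
  scope <- match.arg(scope)
  deg <- degree_sequence(c)
  de <- directed_edges(c)
  de <- de[!duplicated(paste(de$pre, de$post)), , drop = FALSE]
  vals <- cge[cbind(de$pre, de$post)]
  all_vals <- cge[upper.tri(cge)]
  classes <- c("rich", "feed-in", "feed-out", "peripheral")
  out <- list()
  for (k in k_range) {
    hubs <- label_hubs(deg, k)
    is_hub <- stats::setNames(hubs$is_hub, hubs$neuron)
    src <- is_hub[de$pre]; tgt <- is_hub[de$post]
    cls <- ifelse(src & tgt, "rich",
           ifelse(!src & tgt, "feed-in",
           ifelse(src & !tgt, "feed-out", "peripheral")))
    for (cl in classes) {
      v <- vals[cls == cl & !is.na(vals)]
      if (length(v) == 0) {
        out[[length(out) + 1]] <- data.frame(k = k, class = cl,
                                             median_cge = NA_real_, n = 0L,
                                             p = NA_real_, flag = FALSE)
        next
      }
      rest <- if (scope == "connected") vals[cls != cl & !is.na(vals)] else
        all_vals[!is.na(all_vals)]
      p <- if (length(rest) > 0)
        ranksum(v, rest, alternative = "greater")$p else NA_real_
      out[[length(out) + 1]] <- data.frame(
        k = k, class = cl, median_cge = stats::median(v), n = length(v),
        p = p, flag = !is.na(p) && p < 0.05)
    }
  }
  do.call(rbind, out)
}

#' All unordered pairs within a neuron set
#'
#' @param members character vector of neuron names (>= 2).
#' @return two-column matrix of unordered pairs.
#' @export
neuron_pairs <- function(members) {
  if (length(members) < 2) stop_config("need at least 2 neurons")
  idx <- utils::combn(length(members), 2)
  cbind(a = members[idx[1, ]], b = members[idx[2, ]])
}

#' Compare CGE between two disjoint pair sets
#'
#' @param cge a [cge_matrix()].
#' @param set_a,set_b two-column matrices of unordered neuron pairs
#'   (disjoint; masked pairs are dropped from the values).
#' @param test `"ranksum"` or `"welch"`.
#' @param alternative passed to the test (`"greater"` means set_a > set_b).
#' @return a `comparison_result`.
#' @export
compare_pair_sets <- function(cge, set_a, set_b,
                              test = c("ranksum", "welch"),
                              alternative = c("two.sided", "greater", "less")) {
  test <- match.arg(test); alternative <- match.arg(alternative)
  ka <- pair_key(set_a[, 1], set_a[, 2])
  kb <- pair_key(set_b[, 1], set_b[, 2])
  if (length(intersect(ka, kb)) > 0) stop_config("pair sets overlap")
  va <- cge[set_a]; vb <- cge[set_b]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (test == "ranksum") ranksum(va, vb, alternative) else
    welch_t(va, vb, alternative)
}

#' Permutation null from composition-matched random neuron sets
#'
#' Draws `n_perm` random neuron sets matching the attribute composition of
#' `target_set` (e.g. thirteen cholinergic, two glutamatergic and one
#' unknown neuron; or thirteen head and three tail neurons), computes the
#' median pairwise unmasked CGE of each, and reports the add-one
#' permutation p-value for the observed median being high. With
#' `match_on = NULL` the null degenerates to simple random subsets of the
#' same size.
#'
#' @param cge a [cge_matrix()].
#' @param neurons neuron table (for the matching attribute).
#' @param target_set character vector of neuron names.
#' @param match_on column of `neurons` to match on, or `NULL`.
#' @param n_perm number of permutations (default 1e5).
#' @param seed integer seed.
#' @param composition optional named counts per attribute level overriding
#'   the composition derived from `target_set` (a data error is raised when
#'   a level cannot be satisfied from the available neurons).
#' @return a `comparison_result` (`statistic` = observed median;
#'   `median_b` = mean of the null medians), with the null medians in
#'   attribute `null_medians`.
#' @export
composition_matched_null <- function(cge, neurons, target_set, match_on = NULL,
                                     n_perm = 1e5, seed = 1,
                                     composition = NULL) {
  if (!all(target_set %in% neurons$neuron))
    stop_data("unknown neuron in target set")
  set_median <- function(members) {
    pr <- neuron_pairs(members)
    stats::median(cge[pr], na.rm = TRUE)
  }
  observed <- set_median(target_set)
  if (is.null(match_on)) {
    pools <- list(all = neurons$neuron)
    need <- stats::setNames(length(target_set), "all")
  } else {
    attrv <- stats::setNames(as.character(neurons[[match_on]]), neurons$neuron)
    need <- if (is.null(composition)) table(attrv[target_set]) else composition
    pools <- lapply(names(need), function(lv) neurons$neuron[attrv == lv])
    names(pools) <- names(need)
    short <- names(need)[vapply(names(need), function(lv)
      length(pools[[lv]]) < need[[lv]], logical(1))]
    if (length(short) > 0)
      stop_data("composition unsatisfiable for level '%s'", short[1])
  }
  nulls <- with_seed(sub_seed(seed, "compnull"), {
    vapply(seq_len(n_perm), function(i) {
      members <- unlist(lapply(names(need), function(lv)
        sample(pools[[lv]], need[[lv]])), use.names = FALSE)
      set_median(members)
    }, numeric(1))
  })
  p <- perm_p(sum(nulls >= observed, na.rm = TRUE), n_perm)
  res <- comparison_result("permutation", observed, p, "greater",
                           median_a = observed,
                           median_b = mean(nulls, na.rm = TRUE),
                           n_a = length(target_set), n_b = n_perm)
  attr(res, "null_medians") <- nulls
  res
}
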