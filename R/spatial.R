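# Distances, equiprobable binning, connection-probability and CGE vs
# distance curves, bounded exponential fits, residualization.

#' Pairwise Euclidean distances between neurons (um)
#'
#' @param neurons neuron table with `x_um`, `y_um` (2-D positions).
#' @return symmetric distance matrix with neuron dimnames.
#' @export
pairwise_distances <- function(neurons) {
  miss <- neurons$neuron[is.na(neurons$x_um) | is.na(neurons$y_um)]
  if (length(miss) > 0)
    stop_data("missing coordinates for neuron(s): %s",
              paste(utils::head(miss, 5), collapse = ", "))
  d <- as.matrix(stats::dist(neurons[, c("x_um", "y_um")]))
  dimnames(d) <- list(neurons$neuron, neurons$neuron)
  d
}

#' Equiprobable (quantile) bins
#'
#' Partitions `values` into `n_bins` bins containing equal numbers of
#' observations (counts differ by at most 1). Assignment is by sorted
#' position, so ties at a boundary go to the lower bin deterministically.
#'
#' @param values numeric vector.
#' @param n_bins number of bins, `1 <= n_bins <= length(values)`.
#' @return list with `bin` (assignment per value) and `edges` (data.frame
#'   `bin`, `bin_min`, `bin_max`, `bin_center`, `count`).
#' @export
equiprobable_bins <- function(values, n_bins) {
  n <- length(values)
  if (n_bins < 1 || n_bins > n)
    stop_config("n_bins must be between 1 and the number of values")
  if (length(unique(values)) == 1 && n_bins > 1)
    warning("all values identical: only 1 effective bin")
  ord <- order(values)
  sizes <- diff(floor(seq(0, n, length.out = n_bins + 1)))
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), sizes)
  edges <- data.frame(
    bin = seq_len(n_bins),
    bin_min = tapply(values, bin, min),
    bin_max = tapply(values, bin, max),
    count = as.integer(table(factor(bin, levels = seq_len(n_bins)))))
  edges$bin_center <- (edges$bin_min + edges$bin_max) / 2
  list(bin = bin, edges = edges)
}

#' Bounded exponential fit f(x) = A exp(-lambda x) + B
#'
#' Bounded Levenberg-Marquardt least squares with A >= 0, lambda >= 0.
#' Initialization: A0 = max(y) - min(y), B0 = min(y),
#' lambda0 = 1 / median(x); convergence tolerance 1e-8. Degenerate inputs
#' (constant y, or fewer than 4 points) fall back to A = 0, B = mean(y)
#' with a warning.
#'
#' @param x,y numeric vectors (e.g. bin centers and bin values).
#' @return list of class `exponential_fit`: `A`, `lambda`, `B`, `sse`.
#' @export
fit_exponential <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  degenerate <- function(msg) {
    warning(msg)
    structure(list(A = 0, lambda = 0, B = mean(y),
                   sse = sum((y - mean(y))^2)), class = "exponential_fit")
  }
  if (length(x) < 4) return(degenerate("too few points for exponential fit"))
  if (stats::sd(y) == 0)
    return(structure(list(A = 0, lambda = 0, B = y[1], sse = 0),
                     class = "exponential_fit"))
  start <- list(A = max(y) - min(y), lambda = 1 / stats::median(x), B = min(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-lambda * x) + B, start = start,
                      lower = c(A = 0, lambda = 0, B = -Inf),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-8, ptol = 1e-8, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(degenerate("exponential fit failed to converge"))
  cf <- stats::coef(fit)
  structure(list(A = unname(cf["A"]), lambda = unname(cf["lambda"]),
                 B = unname(cf["B"]), sse = sum(stats::resid(fit)^2)),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("f(d) = %.4g * exp(-%.4g d) + %.4g   (sse %.4g)\n",
              x$A, x$lambda, x$B, x$sse))
  invisible(x)
}

predict_exponential <- function(fit, d) fit$A * exp(-fit$lambda * d) + fit$B

#' Connection probability as a function of distance
#'
#' For the stratum of ordered pairs from `source_region` to
#' `target_region`, estimates the probability of connection (any directed
#' connection, gap junctions bidirectional) in equiprobable distance bins,
#' and fits a bounded exponential to the bin centers.
#'
#' @param c a [connectome()].
#' @param d distance matrix from [pairwise_distances()].
#' @param source_region,target_region region labels, or `"all"`.
#' @param n_bins number of equiprobable bins (default 10).
#' @return list with `curve` (data.frame `bin_center`, `bin_min`,
#'   `bin_max`, `value`, `dispersion`, `count`) and `fit`
#'   (an `exponential_fit`, or `NULL` when the stratum is too small).
#' @export
connection_probability_curve <- function(c, d, source_region = "all",
                                         target_region = "all", n_bins = 10) {
  stopifnot(inherits(c, "connectome"))
  nt <- c$neuron_table
  region <- if (!is.null(nt)) stats::setNames(nt$region, nt$neuron) else
    stats::setNames(rep("all", length(c$neurons)), c$neurons)
  src <- if (source_region == "all") c$neurons else
    c$neurons[region[c$neurons] == source_region]
  tgt <- if (target_region == "all") c$neurons else
    c$neurons[region[c$neurons] == target_region]
  if (length(src) == 0 || length(tgt) == 0)
    stop_data("empty stratum %s -> %s", source_region, target_region)
  pairs <- expand.grid(pre = src, post = tgt, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$pre != pairs$post, , drop = FALSE]
  if (nrow(pairs) == 0)
    stop_data("empty stratum %s -> %s", source_region, target_region)
  de <- directed_edges(c)
  ekey <- paste(de$pre, de$post)
  connected <- paste(pairs$pre, pairs$post) %in% ekey
  dist_p <- d[cbind(pairs$pre, pairs$post)]
  if (nrow(pairs) < n_bins) {
    warning("stratum smaller than n_bins: fit skipped")
    return(list(curve = data.frame(bin_center = mean(dist_p),
                                   bin_min = min(dist_p), bin_max = max(dist_p),
                                   value = mean(connected), dispersion = NA,
                                   count = nrow(pairs)),
                fit = NULL))
  }
  bins <- equiprobable_bins(dist_p, n_bins)
  curve <- data.frame(
    bin_center = bins$edges$bin_center,
    bin_min = bins$edges$bin_min, bin_max = bins$edges$bin_max,
    value = as.numeric(tapply(connected, bins$bin, mean)),
    dispersion = as.numeric(tapply(connected, bins$bin,
                                   function(v) stats::sd(v) / sqrt(length(v)))),
    count = bins$edges$count)
  fit <- if (n_bins >= 4) suppressWarnings(
    fit_exponential(curve$bin_center, curve$value)) else NULL
  list(curve = curve, fit = fit)
}

#' CGE as a function of distance
#'
#' For unordered neuron pairs in the requested stratum, reports the mean
#' and standard deviation of unmasked CGE values in equiprobable distance
#' bins (7 by default) with a bounded exponential fit. Masked pairs
#' (bilateral homologs, self, undefined) never contribute.
#'
#' @param cge a [cge_matrix()].
#' @param d distance matrix.
#' @param region_a,region_b region labels defining the stratum of
#'   unordered pairs (both `"all"` for everything); requires the neuron
#'   table via `neurons`.
#' @param neurons neuron table (for regions); `NULL` means no filtering.
#' @param n_bins number of equiprobable bins (default 7).
#' @return list with `curve` and `fit` as in
#'   [connection_probability_curve()].
#' @export
cge_distance_curve <- function(cge, d, region_a = "all", region_b = "all",
                               neurons = NULL, n_bins = 7) {
  nm <- rownames(cge)
  sel_a <- sel_b <- nm
  if (!is.null(neurons) && (region_a != "all" || region_b != "all")) {
    region <- stats::setNames(neurons$region, neurons$neuron)
    if (region_a != "all") sel_a <- nm[region[nm] == region_a]
    if (region_b != "all") sel_b <- nm[region[nm] == region_b]
  }
  pr <- expand.grid(a = sel_a, b = sel_b, stringsAsFactors = FALSE)
  pr <- pr[pr$a < pr$b | (!pr$b %in% sel_a & pr$a != pr$b), , drop = FALSE]
  if (nrow(pr) == 0) stop_data("empty stratum %s - %s", region_a, region_b)
  v <- cge[cbind(pr$a, pr$b)]
  dist_p <- d[cbind(pr$a, pr$b)]
  keep <- !is.na(v)
  v <- v[keep]; dist_p <- dist_p[keep]
  if (length(v) < n_bins) {
    warning("too few unmasked pairs: fit skipped")
    return(list(curve = data.frame(bin_center = mean(dist_p),
                                   bin_min = min(dist_p), bin_max = max(dist_p),
                                   value = mean(v), dispersion = stats::sd(v),
                                   count = length(v)),
                fit = NULL))
  }
  bins <- equiprobable_bins(dist_p, n_bins)
  curve <- data.frame(
    bin_center = bins$edges$bin_center,
    bin_min = bins$edges$bin_min, bin_max = bins$edges$bin_max,
    value = as.numeric(tapply(v, bins$bin, mean)),
    dispersion = as.numeric(tapply(v, bins$bin, stats::sd)),
    count = bins$edges$count)
  fit <- if (n_bins >= 4) suppressWarnings(
    fit_exponential(curve$bin_center, curve$value)) else NULL
  list(curve = curve, fit = fit)
}

#' Residualize values against a fitted exponential distance trend
#'
#' @param values numeric vector (may contain `NA`, which is retained).
#' @param distances numeric vector of the same length.
#' @param fit an `exponential_fit` computed on the same stratum.
#' @return values minus f(distance).
#' @export
residualize <- function(values, distances, fit) {
  if (length(values) != length(distances))
    stop_config("values and distances must have equal length")
  values - predict_exponential(fit, distances)
}
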