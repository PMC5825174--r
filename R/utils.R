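# Internal helpers shared across modules.

#' Derive an independent sub-seed from a global seed and a stream label
#'
#' Each stochastic stage consumes its own stream so that, e.g., changing the
#' number of genes does not perturb the connectome draw. The derivation is a
#' small deterministic integer hash kept below 2^31.
#'
#' @param seed integer global seed.
#' @param label character stream label.
#' @return integer sub-seed.
#' @keywords internal
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587L)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
stop_data <- function(...) stop(sprintf(...), call. = FALSE)

# Canonical unordered pair keys ("a|b" with a < b lexicographically).
pair_key <- function(a, b) {
  lo <- ifelse(a < b, a, b)
  hi <- ifelse(a < b, b, a)
  paste(lo, hi, sep = "|")
}

# Add-one permutation p-value estimator: never zero.
perm_p <- function(n_geq, n_perm) (1 + n_geq) / (n_perm + 1)
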