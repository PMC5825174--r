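# Synthetic connectome + expression generator. Emulates the statistical
# structure of the C. elegans somatic dataset: three spatial clusters of
# neurons (dense head, sparse body, dense tail), a directed binary graph
# with distance-decaying connection probability plus a planted densely
# interconnected hub set, a sparse binary expression matrix with genes
# planted to co-express in hubs, and bilateral homolog pairs with
# near-identical expression profiles.

#' Configuration for the synthetic generator
#'
#' Defaults mirror the anatomy and annotation density of the C. elegans
#' somatic nervous system: 147 head neurons within 130 um, 105 body neurons
#' over 1.02 mm, 27 tail neurons within 90 um, 948 genes, 92 bilateral
#' pairs, and the planted-signal condition used throughout (16 hubs with
#' pairwise connection density 0.8, 20 hub genes expressed at 0.9 in hubs
#' on a 0.05 baseline).
#'
#' @param n_head,n_body,n_tail neuron counts per region.
#' @param head_extent_um,tail_extent_um,body_span_um spatial extents (um).
#' @param decay_rate exponential decay of connection probability (1/um).
#' @param base_prob amplitude A of the connection probability
#'   A exp(-lambda d) + B.
#' @param offset distance-independent offset B.
#' @param n_hubs number of planted hub neurons (sampled from head/tail,
#'   command interneurons first).
#' @param hub_density probability that an unordered hub pair is connected
#'   (reciprocally).
#' @param n_genes number of genes.
#' @param p_base baseline per-(neuron, gene) expression probability.
#' @param n_hub_genes number of genes planted to co-express in hubs.
#' @param p_hub expression probability of planted genes in hub neurons.
#' @param n_bilateral_pairs number of bilateral homolog pairs.
#' @param flip_prob per-entry disagreement probability within a pair.
#' @param gap_fraction fraction of connected pairs stored as gap junctions.
#' @param n_command number of command interneurons (head, all hubs).
#' @param seed integer global seed, expanded into independent per-generator
#'   streams.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_head = 147, n_body = 105, n_tail = 27,
                         head_extent_um = 130, tail_extent_um = 90,
                         body_span_um = 1020,
                         decay_rate = 0.01, base_prob = 0.1, offset = 0.005,
                         n_hubs = 16, hub_density = 0.8,
                         n_genes = 948, p_base = 0.05,
                         n_hub_genes = 20, p_hub = 0.9,
                         n_bilateral_pairs = 92, flip_prob = 0.005,
                         gap_fraction = 0.2, n_command = 10, seed = 1) {
  cfg <- list(n_head = n_head, n_body = n_body, n_tail = n_tail,
              head_extent_um = head_extent_um, tail_extent_um = tail_extent_um,
              body_span_um = body_span_um, decay_rate = decay_rate,
              base_prob = base_prob, offset = offset, n_hubs = n_hubs,
              hub_density = hub_density, n_genes = n_genes, p_base = p_base,
              n_hub_genes = n_hub_genes, p_hub = p_hub,
              n_bilateral_pairs = n_bilateral_pairs, flip_prob = flip_prob,
              gap_fraction = gap_fraction, n_command = n_command, seed = seed)
  counts <- c("n_head", "n_body", "n_tail", "n_hubs", "n_genes",
              "n_hub_genes", "n_bilateral_pairs", "n_command")
  probs <- c("base_prob", "offset", "hub_density", "p_base", "p_hub",
             "flip_prob", "gap_fraction")
  for (f in counts) if (cfg[[f]] < 0) stop_config("%s must be >= 0", f)
  for (f in probs) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop_config("%s must be in [0, 1]", f)
  if (cfg$decay_rate < 0) stop_config("decay_rate must be >= 0")
  for (f in c("head_extent_um", "tail_extent_um", "body_span_um"))
    if (cfg[[f]] < 0) stop_config("%s must be >= 0", f)
  if (cfg$n_hubs > cfg$n_head + cfg$n_tail)
    stop_config("n_hubs must not exceed n_head + n_tail")
  if (cfg$n_hub_genes > cfg$n_genes)
    stop_config("n_hub_genes must not exceed n_genes")
  if (2 * cfg$n_bilateral_pairs > cfg$n_head + cfg$n_body + cfg$n_tail)
    stop_config("too many bilateral pairs for the neuron count")
  if (cfg$n_command > min(cfg$n_hubs, cfg$n_head))
    stop_config("n_command must not exceed min(n_hubs, n_head)")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic neuron annotation table
#'
#' Positions are 2-D (um): a dense head cluster, body neurons spread along
#' the anterior-posterior axis, and a dense tail cluster. Functional types
#' (sensory/motor/interneuron, multi-label allowed; body neurons
#' predominantly motor), neurotransmitter labels, bimodal birth times
#' (early < 550 min, late > 1200 min), command-interneuron flags, and
#' bilateral partner assignments are populated. Deterministic given the
#' config seed.
#'
#' @param config a [synth_config()].
#' @return data.frame with the neuron-table columns consumed by
#'   [load_connectome()].
#' @export
generate_neurons <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(sub_seed(config$seed, "neurons"), {
    n <- config$n_head + config$n_body + config$n_tail
    region <- rep(c("head", "body", "tail"),
                  c(config$n_head, config$n_body, config$n_tail))
    name <- sprintf("%s%03d", c("H", "B", "T")[match(region, c("head", "body", "tail"))],
                    unlist(lapply(c(config$n_head, config$n_body, config$n_tail),
                                  seq_len)))
    half_h <- config$head_extent_um / 2
    half_t <- config$tail_extent_um / 2
    body_start <- half_h + 20
    tail_center <- body_start + config$body_span_um + 20 + half_t
    x <- numeric(n); y <- numeric(n)
    hd <- region == "head"; bd <- region == "body"; tl <- region == "tail"
    x[hd] <- stats::runif(sum(hd), -half_h, half_h)
    y[hd] <- stats::runif(sum(hd), -half_h, half_h)
    x[bd] <- stats::runif(sum(bd), body_start, body_start + config$body_span_um)
    y[bd] <- stats::runif(sum(bd), -20, 20)
    x[tl] <- stats::runif(sum(tl), tail_center - half_t, tail_center + half_t)
    y[tl] <- stats::runif(sum(tl), -half_t, half_t)

    base_type <- character(n)
    base_type[hd] <- sample(c("sensory", "interneuron", "motor"), sum(hd),
                            replace = TRUE, prob = c(0.45, 0.40, 0.15))
    base_type[bd] <- sample(c("motor", "interneuron", "sensory"), sum(bd),
                            replace = TRUE, prob = c(0.75, 0.15, 0.10))
    base_type[tl] <- sample(c("sensory", "interneuron", "motor"), sum(tl),
                            replace = TRUE, prob = c(0.4, 0.4, 0.2))
    second <- stats::runif(n) < 0.06
    types <- base_type
    for (i in which(second)) {
      other <- setdiff(c("sensory", "motor", "interneuron"), base_type[i])
      types[i] <- paste(sort(c(base_type[i], sample(other, 1))), collapse = ";")
    }

    nt <- sample(c("acetylcholine", "glutamate", "GABA", "unknown"), n,
                 replace = TRUE, prob = c(0.45, 0.25, 0.15, 0.15))
    early <- stats::runif(n) < 0.72
    birth <- ifelse(early, stats::runif(n, 0, 550), stats::runif(n, 1200, 3000))

    command <- rep(0L, n)
    if (config$n_command > 0) {
      ci <- sample(which(hd), config$n_command)
      command[ci] <- 1L
      types[ci] <- "interneuron"
      birth[ci] <- stats::runif(config$n_command, 0, 550)
      nt[ci] <- sample(c("acetylcholine", "glutamate"), config$n_command,
                       replace = TRUE, prob = c(0.85, 0.15))
    }

    partner <- rep("", n)
    if (config$n_bilateral_pairs > 0) {
      # pair within regions, proportionally to region size
      quota <- round(config$n_bilateral_pairs *
                       c(config$n_head, config$n_body, config$n_tail) / n)
      quota[1] <- config$n_bilateral_pairs - sum(quota[-1])
      for (r in seq_along(c("head", "body", "tail"))) {
        reg <- c("head", "body", "tail")[r]
        avail <- sample(which(region == reg))
        q <- min(quota[r], floor(length(avail) / 2))
        if (q > 0) {
          a <- avail[seq_len(q)]; b <- avail[q + seq_len(q)]
          partner[a] <- name[b]; partner[b] <- name[a]
        }
      }
    }
    data.frame(neuron = name, x_um = x, y_um = y, region = region,
               types = types, neurotransmitter = nt,
               birth_time_min = round(birth, 1),
               bilateral_partner = partner,
               command_interneuron = command,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic connectome
#'
#' Each ordered non-self pair is connected independently with probability
#' A exp(-lambda d) + B (d the Euclidean distance in um); additionally the
#' designated hub neurons (command interneurons first, then random
#' head/tail neurons) are reciprocally connected with probability
#' `hub_density` per unordered pair. A fraction of connected unordered
#' pairs is stored as undirected gap-junction records, the remainder as
#' directed chemical records. Deterministic given the config seed.
#'
#' @param neurons output of [generate_neurons()].
#' @param config a [synth_config()].
#' @return a [connectome()] with attribute `hubs` (planted hub names).
#' @export
generate_connectome <- function(neurons, config) {
  stopifnot(inherits(config, "synth_config"))
  if (any(is.na(neurons$x_um)) || any(is.na(neurons$y_um)))
    stop_data("neurons lacking positions")
  with_seed(sub_seed(config$seed, "connectome"), {
    n <- nrow(neurons)
    d <- as.matrix(stats::dist(neurons[, c("x_um", "y_um")]))
    p <- pmin(config$base_prob * exp(-config$decay_rate * d) + config$offset, 1)
    diag(p) <- 0
    adj <- matrix(stats::runif(n * n) < p, n, n)
    diag(adj) <- FALSE

    hubs <- character(0)
    if (config$n_hubs > 0) {
      ci <- which(neurons$command_interneuron == 1)
      pool <- setdiff(which(neurons$region %in% c("head", "tail")), ci)
      extra <- config$n_hubs - length(ci)
      hub_idx <- c(ci, if (extra > 0) sample(pool, extra))
      hub_idx <- hub_idx[seq_len(config$n_hubs)]
      hubs <- neurons$neuron[hub_idx]
      hp <- utils::combn(hub_idx, 2)
      on <- stats::runif(ncol(hp)) < config$hub_density
      adj[cbind(hp[1, on], hp[2, on])] <- TRUE
      adj[cbind(hp[2, on], hp[1, on])] <- TRUE
    }

    idx <- which(adj, arr.ind = TRUE)
    key <- pair_key(neurons$neuron[idx[, 1]], neurons$neuron[idx[, 2]])
    pairs <- unique(key)
    n_gap <- floor(config$gap_fraction * length(pairs))
    gap_keys <- if (n_gap > 0) sample(pairs, n_gap) else character(0)
    is_gap <- key %in% gap_keys
    chem_idx <- idx[!is_gap, , drop = FALSE]
    chem <- data.frame(pre = neurons$neuron[chem_idx[, 1]],
                       post = neurons$neuron[chem_idx[, 2]],
                       weight = 1 + stats::rpois(nrow(chem_idx), 2),
                       stringsAsFactors = FALSE)
    gap <- if (n_gap > 0) {
      parts <- strsplit(gap_keys, "|", fixed = TRUE)
      data.frame(a = vapply(parts, `[`, "", 1),
                 b = vapply(parts, `[`, "", 2),
                 weight = 1 + stats::rpois(n_gap, 2),
                 stringsAsFactors = FALSE)
    } else NULL
    cn <- connectome(neurons$neuron, chem = chem, gap = gap,
                     neuron_table = neurons)
    attr(cn, "hubs") <- hubs
    cn
  })
}

#' Generate a synthetic binary expression matrix
#'
#' Entries are independent Bernoulli(p_base); planted hub genes are then
#' redrawn as Bernoulli(p_hub) in hub neurons; finally each bilateral
#' partner receives a copy of its partner's row with entries flipped
#' independently with probability `flip_prob` (so homologs are exact copies
#' when `flip_prob = 0`, including any planted signal). Deterministic given
#' the config seed.
#'
#' @param neurons output of [generate_neurons()].
#' @param hubs character vector of hub neuron names (subset of neurons).
#' @param config a [synth_config()].
#' @return binary neurons x genes matrix with attribute `planted_genes`.
#' @export
generate_expression <- function(neurons, hubs, config) {
  stopifnot(inherits(config, "synth_config"))
  if (!all(hubs %in% neurons$neuron))
    stop_data("unknown hub id '%s'", setdiff(hubs, neurons$neuron)[1])
  with_seed(sub_seed(config$seed, "expression"), {
    n <- nrow(neurons); g <- config$n_genes
    genes <- sprintf("g%04d", seq_len(g))
    e <- matrix(stats::rbinom(n * g, 1, config$p_base), n, g,
                dimnames = list(neurons$neuron, genes))
    planted <- character(0)
    if (config$n_hub_genes > 0 && length(hubs) > 0) {
      planted <- sample(genes, config$n_hub_genes)
      e[hubs, planted] <- stats::rbinom(length(hubs) * config$n_hub_genes,
                                        1, config$p_hub)
    }
    # bilateral homologs: symmetric flips of the partner's row
    partner <- neurons$bilateral_partner
    done <- character(0)
    for (i in seq_len(n)) {
      p <- partner[i]
      if (!nzchar(p) || neurons$neuron[i] %in% done) next
      j <- match(p, neurons$neuron)
      flip <- stats::runif(g) < config$flip_prob
      e[j, ] <- ifelse(flip, 1L - e[i, ], e[i, ])
      done <- c(done, neurons$neuron[i], p)
    }
    attr(e, "planted_genes") <- planted
    e
  })
}

#' Generate a full synthetic dataset and optionally write it to disk
#'
#' Runs the three generators, adds a symmetric lineage-distance matrix of
#' small random integers, and (if `out_dir` is given) writes the TSV/CSV
#' files consumed by the loaders plus a JSON sidecar recording config and
#' seed.
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory.
#' @return list with `neurons`, `connectome`, `hubs`, `expression`,
#'   `planted_genes`, `lineage`, `config`.
#' @export
simulate_dataset <- function(config = synth_config(), out_dir = NULL) {
  neurons <- generate_neurons(config)
  cn <- generate_connectome(neurons, config)
  hubs <- attr(cn, "hubs")
  e <- generate_expression(neurons, hubs, config)
  n <- nrow(neurons)
  lineage <- with_seed(sub_seed(config$seed, "lineage"), {
    m <- matrix(sample(2:14, n * n, replace = TRUE), n, n,
                dimnames = list(neurons$neuron, neurons$neuron))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    m
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_connectome(cn, file.path(out_dir, "edges.tsv"),
                     file.path(out_dir, "neurons.tsv"))
    idx <- which(e == 1, arr.ind = TRUE)
    utils::write.table(
      data.frame(neuron = rownames(e)[idx[, 1]], gene = colnames(e)[idx[, 2]]),
      file.path(out_dir, "expression.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.csv(lineage, file.path(out_dir, "lineage.csv"), quote = FALSE)
    jsonlite::write_json(
      list(config = unclass(config), hubs = hubs,
           planted_genes = attr(e, "planted_genes")),
      file.path(out_dir, "config.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  list(neurons = neurons, connectome = cn, hubs = hubs, expression = e,
       planted_genes = attr(e, "planted_genes"), lineage = lineage,
       config = config)
}

#' Bilateral pairs of a neuron table
#'
#' @param neurons a neuron table with `bilateral_partner`.
#' @return two-column matrix of unordered pairs (each pair once).
#' @export
bilateral_pairs <- function(neurons) {
  has <- nzchar(neurons$bilateral_partner) & !is.na(neurons$bilateral_partner)
  a <- neurons$neuron[has]; b <- neurons$bilateral_partner[has]
  keep <- a < b
  cbind(a = a[keep], b = b[keep])
}
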