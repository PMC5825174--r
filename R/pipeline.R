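# End-to-end orchestration: load or simulate, spatial curves, rich club,
# modularity, CGE, edge-class and driver comparisons, gene scoring, ORA.

#' Default pipeline configuration
#'
#' Defaults mirror the analysis' standard choices: hub threshold k = 44,
#' 1000 rewiring nulls at 50 swaps per edge, 10 distance bins for
#' connection probability and 7 for CGE, minimum match count 10 and hit
#' threshold 1e-4 for gene scoring.
#'
#' @param simulate list of [synth_config()] arguments (synthetic input), or
#'   `NULL` when `inputs` is given.
#' @param inputs list with `edge_tsv`, `neuron_tsv`, `expression_tsv` (and
#'   optionally `lineage_csv`), or `NULL`.
#' @param seed integer seed (mandatory for stochastic stages).
#' @param k_threshold,n_null,iters_per_edge,n_module_runs,n_perm,bins_conn,bins_cge,method,alpha,min_n,out_dir
#'   stage parameters; see the corresponding stage functions.
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(simulate = list(), inputs = NULL, seed = 1,
                            k_threshold = 44, n_null = 1000,
                            iters_per_edge = 50, n_module_runs = 1000,
                            n_perm = 1e5, bins_conn = 10, bins_cge = 7,
                            method = "r_phi", alpha = 1e-4, min_n = 10,
                            out_dir = NULL) {
  list(simulate = simulate, inputs = inputs, seed = seed,
       k_threshold = k_threshold, n_null = n_null,
       iters_per_edge = iters_per_edge, n_module_runs = n_module_runs,
       n_perm = n_perm, bins_conn = bins_conn, bins_cge = bins_cge,
       method = method, alpha = alpha, min_n = min_n, out_dir = out_dir)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load or simulate the dataset; connection-probability
#' and CGE distance curves; normalized rich-club curve; Louvain consensus
#' modularity; CGE matrix with bilateral exclusion; edge-class CGE
#' comparisons; driver analyses (interneurons, modules, birth time,
#' lineage, neurotransmitter- and location-matched permutation nulls,
#' command interneurons); gene-contribution scoring for both comparisons.
#' All stage outputs are returned (and written as TSV/JSON under
#' `config$out_dir` if set) together with a machine-readable summary.
#'
#' @param config a [pipeline_config()].
#' @return named list of stage results plus `summary`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop_config("config$seed is mandatory")
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (!has_sim && !has_inp)
    stop_config("config must provide either a simulate block or inputs")

  log_stage <- function(...) message(sprintf(...))

  # --- load or simulate -------------------------------------------------
  if (has_inp) {
    log_stage("stage load: %s", config$inputs$edge_tsv)
    cn <- load_connectome(config$inputs$edge_tsv, config$inputs$neuron_tsv,
                          quiet = TRUE)
    neurons <- cn$neuron_table
    expr <- read_expression(config$inputs$expression_tsv,
                            neurons = cn$neurons)
    lineage <- if (!is.null(config$inputs$lineage_csv))
      as.matrix(utils::read.csv(config$inputs$lineage_csv, row.names = 1,
                                check.names = FALSE)) else NULL
    planted <- character(0)
    hubs_planted <- character(0)
  } else {
    log_stage("stage simulate (seed %d)", config$seed)
    sc <- do.call(synth_config, c(config$simulate,
                                  if (is.null(config$simulate$seed))
                                    list(seed = config$seed)))
    ds <- simulate_dataset(sc)
    cn <- ds$connectome; neurons <- ds$neurons; expr <- ds$expression
    lineage <- ds$lineage; planted <- ds$planted_genes
    hubs_planted <- ds$hubs
  }
  bil <- bilateral_pairs(neurons)
  deg <- degree_sequence(cn)
  hubs_tab <- label_hubs(deg, config$k_threshold)
  hub_names <- hubs_tab$neuron[hubs_tab$is_hub]

  # --- spatial ----------------------------------------------------------
  log_stage("stage spatial")
  d <- pairwise_distances(neurons)
  regions <- intersect(c("head", "body", "tail"), unique(neurons$region))
  conn_curves <- list()
  for (r1 in regions) for (r2 in regions) {
    key <- paste(r1, r2, sep = "->")
    conn_curves[[key]] <- tryCatch(
      connection_probability_curve(cn, d, r1, r2, n_bins = config$bins_conn),
      error = function(e) NULL)
  }

  # --- rich club --------------------------------------------------------
  log_stage("stage richclub (%d nulls)", config$n_null)
  rc <- normalized_rich_club(cn, n_null = config$n_null,
                             iters_per_edge = config$iters_per_edge,
                             seed = sub_seed(config$seed, "richclub"))

  # --- modularity -------------------------------------------------------
  log_stage("stage modularity (%d runs)", config$n_module_runs)
  part <- louvain_consensus(cn, n_runs = max(2, config$n_module_runs),
                            seed = sub_seed(config$seed, "modularity"))

  # --- CGE --------------------------------------------------------------
  log_stage("stage cge (%s)", config$method)
  cge <- cge_matrix(expr, method = config$method, bilateral_pairs = bil)
  cge_curves <- list()
  for (r in regions) {
    cge_curves[[paste0(r, "-", r)]] <- tryCatch(
      cge_distance_curve(cge, d, r, r, neurons = neurons,
                         n_bins = config$bins_cge),
      error = function(e) NULL)
  }

  # --- edge classes -----------------------------------------------------
  log_stage("stage edge classes")
  kmax <- max(deg$k)
  k_grid <- sort(unique(round(stats::quantile(deg$k, seq(0.5, 0.98, by = 0.04)))))
  k_grid <- k_grid[k_grid < kmax]
  class_curve <- edge_class_cge_curve(cge, cn, k_grid)
  cp <- connected_pairs(cn)
  cp_key <- pair_key(cp$a, cp$b)
  cp_keep <- !cp_key %in% pair_key(bil[, 1], bil[, 2])
  cpk <- cp[cp_keep, , drop = FALSE]
  is_hub <- stats::setNames(hubs_tab$is_hub, hubs_tab$neuron)
  rich_sel <- is_hub[cpk$a] & is_hub[cpk$b]
  peri_sel <- !is_hub[cpk$a] & !is_hub[cpk$b]
  rich_vs_peripheral <- if (sum(rich_sel) >= 1 && sum(peri_sel) >= 1)
    compare_pair_sets(cge,
                      cbind(cpk$a[rich_sel], cpk$b[rich_sel]),
                      cbind(cpk$a[peri_sel], cpk$b[peri_sel]),
                      test = "ranksum", alternative = "greater") else NULL

  # connected vs unconnected
  universe <- neuron_pair_universe(cn$neurons, exclude = bil)
  conn_key <- pair_key(cpk$a, cpk$b)
  is_conn <- pair_key(universe[, 1], universe[, 2]) %in% conn_key
  connected_vs_unconnected <- compare_pair_sets(
    cge, universe[is_conn, , drop = FALSE], universe[!is_conn, , drop = FALSE],
    test = "ranksum", alternative = "greater")

  # --- drivers ----------------------------------------------------------
  log_stage("stage drivers (%g permutations)", config$n_perm)
  drivers <- list()
  mp <- module_pair_sets(cn, part, exclude_pairs = bil)
  in_intra <- function(pairs) {
    rich <- is_hub[pairs[, 1]] & is_hub[pairs[, 2]]
    list(rich = pairs[rich, , drop = FALSE],
         nonrich = pairs[!rich, , drop = FALSE])
  }
  sp_in <- in_intra(mp$intra)
  if (nrow(sp_in$rich) >= 1 && nrow(sp_in$nonrich) >= 1)
    drivers$intra_module_rich_vs_nonrich <- compare_pair_sets(
      cge, sp_in$rich, sp_in$nonrich, "ranksum", "greater")
  sp_out <- in_intra(mp$inter)
  if (nrow(sp_out$rich) >= 1 && nrow(sp_out$nonrich) >= 1)
    drivers$inter_module_rich_vs_nonrich <- compare_pair_sets(
      cge, sp_out$rich, sp_out$nonrich, "ranksum", "greater")

  if (!is.null(lineage)) {
    ut <- upper.tri(cge)
    ok <- !is.na(cge[ut])
    drivers$lineage_spearman <- spearman(lineage[rownames(cge),
                                                 colnames(cge)][ut][ok],
                                         cge[ut][ok])
  }

  early <- stats::setNames(neurons$birth_time_min < 550, neurons$neuron)
  eb <- cpk[early[cpk$a] & early[cpk$b], , drop = FALSE]
  if (nrow(eb) > 1) {
    eb_rich <- is_hub[eb$a] & is_hub[eb$b]
    if (sum(eb_rich) >= 1 && sum(!eb_rich) >= 1)
      drivers$early_born_rich_vs_nonrich <- compare_pair_sets(
        cge, cbind(eb$a[eb_rich], eb$b[eb_rich]),
        cbind(eb$a[!eb_rich], eb$b[!eb_rich]), "ranksum", "greater")
  }

  if (length(hub_names) >= 3) {
    drivers$hub_neurotransmitter_null <- tryCatch(
      composition_matched_null(cge, neurons, hub_names,
                               match_on = "neurotransmitter",
                               n_perm = config$n_perm,
                               seed = sub_seed(config$seed, "nt")),
      error = function(e) NULL)
    drivers$hub_location_null <- tryCatch(
      composition_matched_null(cge, neurons, hub_names, match_on = "region",
                               n_perm = config$n_perm,
                               seed = sub_seed(config$seed, "loc")),
      error = function(e) NULL)
    cmd <- neurons$neuron[neurons$command_interneuron == 1]
    cmd_hubs <- intersect(cmd, hub_names)
    other_hubs <- setdiff(hub_names, cmd)
    if (length(cmd_hubs) >= 2 && length(other_hubs) >= 2)
      drivers$command_vs_other_hubs <- compare_pair_sets(
        cge, neuron_pairs(cmd_hubs), neuron_pairs(other_hubs),
        "ranksum", "greater")
  }

  # --- gene scoring -----------------------------------------------------
  log_stage("stage gene scoring")
  gs_conn <- score_genes(expr, cn, "connected_vs_unconnected",
                         k_threshold = config$k_threshold,
                         min_n = config$min_n, alpha = config$alpha,
                         exclude_pairs = bil)
  gs_hub <- score_genes(expr, cn, "hub_involved_vs_peripheral",
                        k_threshold = config$k_threshold,
                        min_n = config$min_n, alpha = config$alpha,
                        exclude_pairs = bil)

  # --- summary ----------------------------------------------------------
  sig <- !is.na(rc$p_perm) & rc$p_perm < 0.05 & !is.na(rc$phi_norm) &
    rc$phi_norm > 1
  planted_recovery <- NA_real_
  if (length(planted) > 0) {
    ord <- rank(gs_hub$p_a, ties.method = "min")
    top <- ord <= ceiling(0.1 * nrow(gs_hub))
    planted_recovery <- sum(top[match(planted, gs_hub$gene)])
  }
  summary <- list(
    n_neurons = length(cn$neurons),
    n_directed_connections = nrow(unique(cbind(directed_edges(cn)$pre,
                                               directed_edges(cn)$post))),
    n_connected_pairs = nrow(cp),
    n_hubs = length(hub_names),
    k_threshold = config$k_threshold,
    rich_club_significant_k = rc$k[sig],
    max_phi_norm = if (any(!is.na(rc$phi_norm))) max(rc$phi_norm, na.rm = TRUE)
      else NA_real_,
    n_modules = max(part$membership),
    modularity_Q = part$Q,
    median_cge_rich = if (!is.null(rich_vs_peripheral))
      rich_vs_peripheral$median_a else NA_real_,
    median_cge_peripheral = if (!is.null(rich_vs_peripheral))
      rich_vs_peripheral$median_b else NA_real_,
    p_rich_vs_peripheral = if (!is.null(rich_vs_peripheral))
      rich_vs_peripheral$p else NA_real_,
    p_connected_vs_unconnected = connected_vs_unconnected$p,
    p_class_connected = attr(gs_conn, "p_class"),
    p_class_hub = attr(gs_hub, "p_class"),
    genes_min_n_connected = sum(gs_conn$passes_min_n),
    genes_min_n_hub = sum(gs_hub$passes_min_n),
    planted_genes_in_top_decile = planted_recovery,
    n_planted_genes = length(planted),
    seed = config$seed)

  out <- list(connectome = cn, neurons = neurons, expression = expr,
              degrees = deg, hubs = hub_names, planted_hubs = hubs_planted,
              conn_curves = conn_curves, cge_curves = cge_curves,
              rich_club = rc, partition = part, cge = cge,
              class_curve = class_curve,
              rich_vs_peripheral = rich_vs_peripheral,
              connected_vs_unconnected = connected_vs_unconnected,
              drivers = drivers, gene_scores_connected = gs_conn,
              gene_scores_hub = gs_hub, summary = summary)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(deg, "degrees.tsv")
    wt(as.data.frame(rc), "rich_club.tsv")
    wt(data.frame(neuron = names(part$membership),
                  module = part$membership), "modules.tsv")
    wt(class_curve, "edge_class_cge.tsv")
    wt(as.data.frame(gs_conn), "gene_scores_connected.tsv")
    wt(as.data.frame(gs_hub), "gene_scores_hub.tsv")
    write_cge(cge, file.path(config$out_dir, "cge.tsv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
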