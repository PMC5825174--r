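test_that("generated neuron tables honor region counts and determinism", {
  cfg <- synth_config(seed = 2)
  nt <- generate_neurons(cfg)
  expect_equal(nrow(nt), 279)
  expect_equal(as.integer(table(nt$region)[c("head", "body", "tail")]),
               c(147, 105, 27))
  # spatial extents
  hd <- nt[nt$region == "head", ]
  expect_true(max(dist(hd[, c("x_um", "y_um")])) <= cfg$head_extent_um * sqrt(2))
  tl <- nt[nt$region == "tail", ]
  expect_true(max(dist(tl[, c("x_um", "y_um")])) <= cfg$tail_extent_um * sqrt(2))
  # birth times bimodal
  expect_true(all(nt$birth_time_min < 550 | nt$birth_time_min > 1200))
  # command interneurons: head, interneuron, early born
  ci <- nt[nt$command_interneuron == 1, ]
  expect_equal(nrow(ci), 10)
  expect_true(all(ci$region == "head"))
  expect_true(all(ci$types == "interneuron"))
  expect_true(all(ci$birth_time_min < 550))
  # bilateral partner symmetry
  has <- nzchar(nt$bilateral_partner)
  p <- setNames(nt$bilateral_partner, nt$neuron)
  expect_true(all(p[p[has]] == nt$neuron[has]))

  # degenerate config: all head
  nt5 <- generate_neurons(synth_config(n_head = 5, n_body = 0, n_tail = 0,
                                       n_hubs = 2, n_bilateral_pairs = 0,
                                       n_command = 2, seed = 1))
  expect_equal(nrow(nt5), 5)
  expect_true(all(nt5$region == "head"))

  # determinism: identical (config, seed) => identical outputs
  expect_identical(generate_neurons(cfg), generate_neurons(cfg))
  expect_false(identical(generate_neurons(synth_config(seed = 3)), nt))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_head = -1), "n_head")
  expect_error(synth_config(p_hub = 1.2), "p_hub")
  expect_error(synth_config(n_hubs = 200), "n_hubs")
  expect_error(synth_config(n_hub_genes = 1000), "n_hub_genes")
  expect_error(synth_config(head_extent_um = -5), "head_extent_um")
})

test_that("distance-free limit: empirical density matches the target probability", {
  p <- 0.08
  cfg <- synth_config(n_head = 60, n_body = 40, n_tail = 20,
                      decay_rate = 0, base_prob = p, offset = 0,
                      n_hubs = 0, gap_fraction = 0, n_bilateral_pairs = 0,
                      n_genes = 5, n_hub_genes = 0, n_command = 0, seed = 6)
  cn <- generate_connectome(generate_neurons(cfg), cfg)
  n <- 120
  n_pairs <- n * (n - 1)
  dens <- nrow(directed_edges(cn)) / n_pairs
  se <- sqrt(p * (1 - p) / n_pairs)
  expect_lt(abs(dens - p), 3 * se)
})

test_that("hub_density = 1 gives a complete hub subgraph with phi = 1", {
  cfg <- synth_config(n_head = 40, n_body = 10, n_tail = 10, n_hubs = 8,
                      hub_density = 1, n_genes = 5, n_hub_genes = 0, n_bilateral_pairs = 0,
                      n_command = 4, seed = 8)
  cn <- generate_connectome(generate_neurons(cfg), cfg)
  hubs <- attr(cn, "hubs")
  cp <- connected_pairs(cn)
  hub_pairs <- nemacge:::pair_key(cp$a, cp$b)[cp$a %in% hubs & cp$b %in% hubs]
  expect_equal(length(hub_pairs), choose(8, 2))
  # phi over exactly the hub set: threshold at the smallest hub degree - 1
  deg <- degree_sequence(cn)
  kmin <- min(deg$k[deg$neuron %in% hubs])
  if (sum(deg$k > kmin - 1) == length(hubs))
    expect_equal(rich_club_phi(cn, kmin - 1), 1)
})

test_that("planted hubs have elevated expected degree across seeds", {
  diffs <- sapply(1:20, function(s) {
    cfg <- synth_config(n_head = 50, n_body = 30, n_tail = 15, n_hubs = 8,
                        hub_density = 0.8, base_prob = 0.05, n_genes = 5, n_hub_genes = 0,
                        n_bilateral_pairs = 0, n_command = 4, seed = s)
    cn <- generate_connectome(generate_neurons(cfg), cfg)
    deg <- degree_sequence(cn)
    hubs <- attr(cn, "hubs")
    mean(deg$k[deg$neuron %in% hubs]) - mean(deg$k[!deg$neuron %in% hubs])
  })
  expect_true(all(diffs > 0))
})

test_that("expression baseline density matches the binomial mean", {
  cfg <- synth_config(p_base = 0.03, n_hub_genes = 0, n_bilateral_pairs = 0,
                      seed = 12)
  nt <- generate_neurons(cfg)
  e <- generate_expression(nt, hubs = character(0), cfg)
  per_neuron <- rowSums(e)
  se <- sqrt(948 * 0.03 * 0.97 / 279)
  expect_lt(abs(mean(per_neuron) - 948 * 0.03), 3 * se)
})

test_that("saturated planting forces all matches onto hub pairs", {
  cfg <- synth_config(n_head = 30, n_body = 10, n_tail = 5, n_hubs = 6,
                      n_genes = 30, n_hub_genes = 5, p_hub = 1, p_base = 0,
                      n_bilateral_pairs = 0, n_command = 3, seed = 9)
  nt <- generate_neurons(cfg)
  cn <- generate_connectome(nt, cfg)
  hubs <- attr(cn, "hubs")
  e <- generate_expression(nt, hubs, cfg)
  planted <- attr(e, "planted_genes")
  deg <- degree_sequence(cn)
  kthr <- sort(deg$k, decreasing = TRUE)[length(hubs) + 1]
  gs <- score_genes(e, cn, "hub_involved_vs_peripheral", k_threshold = kthr)
  sel <- gs$gene %in% planted
  expect_true(all(gs$m[sel] == gs$n[sel]))
  expect_true(all(gs$n[!sel] == 0))
  expect_error(generate_expression(nt, c(hubs, "nope"), cfg), "nope")
})

test_that("simulate_dataset writes loadable files and a config sidecar", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_head = 30, n_body = 10, n_tail = 8, n_hubs = 4,
                      n_genes = 40, n_hub_genes = 4, n_bilateral_pairs = 5,
                      n_command = 2, seed = 5)
  ds <- simulate_dataset(cfg, out_dir = dir)
  cn <- load_connectome(file.path(dir, "edges.tsv"),
                        file.path(dir, "neurons.tsv"), quiet = TRUE)
  expect_identical(degree_sequence(cn)$k, degree_sequence(ds$connectome)$k)
  e <- read_expression(file.path(dir, "expression.tsv"),
                       neurons = cn$neurons)
  expect_equal(sum(e), sum(ds$expression))
  side <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(side$config$seed, 5)
  expect_equal(sort(unlist(side$hubs)), sort(ds$hubs))
})
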