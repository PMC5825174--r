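test_that("pairwise distances are Euclidean and satisfy the triangle inequality", {
  nt <- data.frame(neuron = c("A", "B", "C"), x_um = c(0, 3, 0),
                   y_um = c(0, 4, 0), region = "head")
  d <- pairwise_distances(nt)
  expect_equal(d["A", "B"], 5)
  expect_equal(d["A", "C"], 0)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))

  set.seed(55)
  nt2 <- data.frame(neuron = sprintf("n%d", 1:15), x_um = runif(15, 0, 100),
                    y_um = runif(15, 0, 100), region = "head")
  d2 <- pairwise_distances(nt2)
  for (i in 1:15) for (j in 1:15) for (k in 1:15)
    expect_lte(d2[i, j], d2[i, k] + d2[k, j] + 1e-9)

  nt$x_um[2] <- NA
  expect_error(pairwise_distances(nt), "B")
})

test_that("equiprobable bins have near-equal occupancy", {
  b <- equiprobable_bins(1:10, 5)
  expect_equal(as.integer(table(b$bin)), rep(2, 5))
  set.seed(7)
  v <- runif(1000)
  b2 <- equiprobable_bins(v, 10)
  expect_true(all(table(b2$bin) == 100))
  # uneven division: counts differ by at most 1
  b3 <- equiprobable_bins(runif(103), 10)
  expect_lte(diff(range(table(b3$bin))), 1)
  expect_error(equiprobable_bins(1:3, 5), "n_bins")
  expect_warning(equiprobable_bins(rep(1, 10), 3), "identical")
})

test_that("exponential fit recovers noiseless parameters exactly", {
  x <- seq(10, 500, length.out = 20)
  y <- 0.3 * exp(-0.01 * x) + 0.02
  f <- fit_exponential(x, y)
  expect_equal(f$A, 0.3, tolerance = 1e-6)
  expect_equal(f$lambda, 0.01, tolerance = 1e-6)
  expect_equal(f$B, 0.02, tolerance = 1e-6)
  expect_lt(f$sse, 1e-12)
  # constant data: A = 0
  f0 <- fit_exponential(x, rep(0.5, 20))
  expect_equal(f0$A, 0)
  expect_equal(f0$B, 0.5)
})

test_that("connection probability curve equals direct counting and recovers the generative model", {
  cfg <- synth_config(n_head = 35, n_body = 25, n_tail = 15, n_hubs = 0,
                      decay_rate = 0.005, base_prob = 0.3, offset = 0.02,
                      n_genes = 5, n_hub_genes = 0, n_bilateral_pairs = 0, gap_fraction = 0,
                      n_command = 0, seed = 13)
  nt <- generate_neurons(cfg)
  cn <- generate_connectome(nt, cfg)
  d <- pairwise_distances(nt)
  out <- connection_probability_curve(cn, d, "all", "all", n_bins = 8)
  # oracle: the binned probabilities must aggregate to a direct count over
  # the stratum's ordered pair list, with equiprobable occupancy
  de <- directed_edges(cn)
  n_pairs <- nrow(nt) * (nrow(nt) - 1)
  expect_equal(sum(out$curve$value * out$curve$count), nrow(de),
               tolerance = 1e-9)
  expect_equal(sum(out$curve$count), n_pairs)
  expect_lte(diff(range(out$curve$count)), 1)
  # pairs strictly inside bin 1's extent are counted there
  b1 <- out$curve[1, ]
  pairs <- expand.grid(pre = nt$neuron, post = nt$neuron,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$pre != pairs$post, ]
  dv <- d[cbind(pairs$pre, pairs$post)]
  expect_gte(b1$count, sum(dv > b1$bin_min & dv < b1$bin_max))
  expect_true(all(out$curve$value >= 0 & out$curve$value <= 1))
  expect_true(out$fit$lambda >= 0 && out$fit$A >= 0)
})

test_that("distance-free graphs give a flat connection curve with lambda near 0", {
  cfg <- synth_config(n_head = 40, n_body = 30, n_tail = 10, n_hubs = 0,
                      decay_rate = 0, base_prob = 0.1, offset = 0,
                      n_genes = 5, n_hub_genes = 0, n_bilateral_pairs = 0, gap_fraction = 0,
                      n_command = 0, seed = 14)
  nt <- generate_neurons(cfg)
  cn <- generate_connectome(nt, cfg)
  out <- connection_probability_curve(cn, pairwise_distances(nt),
                                      n_bins = 8)
  se <- sqrt(0.1 * 0.9 / min(out$curve$count))
  expect_true(all(abs(out$curve$value - 0.1) < 4 * se))
  expect_lt(out$fit$A * exp(-out$fit$lambda * out$curve$bin_center[1]) -
              out$fit$A * exp(-out$fit$lambda * max(out$curve$bin_center)),
            3 * se)  # fitted decay is negligible across the range
})

test_that("CGE distance curves respect masks and degenerate strata warn", {
  cfg <- synth_config(n_head = 30, n_body = 10, n_tail = 8, n_hubs = 0,
                      n_genes = 200, p_base = 0.1, n_bilateral_pairs = 6,
                      n_command = 0, seed = 15)
  nt <- generate_neurons(cfg)
  e <- generate_expression(nt, character(0), cfg)
  bil <- bilateral_pairs(nt)
  cge <- cge_matrix(e, "r_phi", bilateral_pairs = bil)
  d <- pairwise_distances(nt)
  out <- cge_distance_curve(cge, d, "head", "head", neurons = nt, n_bins = 5)
  # masked pairs never contribute
  n_head_pairs <- choose(30, 2)
  n_masked_head <- sum(bil[, 1] %in% nt$neuron[nt$region == "head"])
  n_undef <- sum(is.na(cge[t(combn(nt$neuron[nt$region == "head"], 2))])) -
    n_masked_head
  expect_equal(sum(out$curve$count), n_head_pairs - n_masked_head - n_undef)
  # constant CGE: flat curve with A ~ 0
  cge_const <- cge
  cge_const[!is.na(cge_const)] <- 0.25
  out_c <- cge_distance_curve(cge_const, d, n_bins = 5)
  expect_true(all(abs(out_c$curve$value - 0.25) < 1e-12))
  expect_lt(out_c$fit$A, 1e-6)
})

test_that("residualization is exact on the curve and linear in shifts", {
  fit <- structure(list(A = 0.5, lambda = 0.02, B = 0.1, sse = 0),
                   class = "exponential_fit")
  d <- c(10, 50, 200)
  on_curve <- 0.5 * exp(-0.02 * d) + 0.1
  expect_equal(residualize(on_curve, d, fit), rep(0, 3), tolerance = 1e-12)
  expect_equal(residualize(on_curve + 0.3, d, fit), rep(0.3, 3),
               tolerance = 1e-12)
  # planted nearby high-CGE pairs drag the fit: residuals of non-negative
  # values can go strictly negative (the artifact the correction exhibits)
  dd <- seq(5, 300, length.out = 50)
  vals <- rep(0.05, 50)
  vals[dd < 40] <- 0.8
  f2 <- fit_exponential(dd, vals)
  res <- residualize(vals, dd, f2)
  expect_true(any(res < 0))
})
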