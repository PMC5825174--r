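test_that("rank-sum p-values match exact enumeration on tiny samples", {
  # all three ranks of b above a: p = 1 / C(6,3) * ... = 1/20
  r <- ranksum(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
  expect_equal(r$p, 1 / 20, tolerance = 1e-12)
  # single observation above three: p = 1/4
  r2 <- ranksum(5, c(1, 2, 3), alternative = "greater")
  expect_equal(r2$p, 1 / 4, tolerance = 1e-12)
  r3 <- ranksum(c(1, 2, 3), c(1, 2, 3), alternative = "two.sided")
  expect_equal(r3$p, 1)
  expect_error(ranksum(numeric(0), 1:3), "empty")
})

test_that("exact and approximate rank-sum modes agree for moderate samples", {
  set.seed(99)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30, 0.3)
    pe <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
    pa <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("Welch test behaves at its boundary cases", {
  set.seed(17)
  ps <- replicate(200, welch_t(rnorm(15), rnorm(15),
                               alternative = "greater")$p)
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_lt(welch_t(rnorm(30, 10), rnorm(30), alternative = "greater")$p,
            1e-6)
  r <- welch_t(rep(2, 5), rep(2, 5))
  expect_true(is.na(r$p))
  expect_error(welch_t(1, 1:5), ">= 2")
})

test_that("Spearman correlation handles ranks, reversals, and constants", {
  expect_equal(spearman(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman(1:10, rev(1:10))$statistic, -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))$statistic, 0.6,
               tolerance = 1e-12)
  expect_true(is.na(spearman(rep(1, 5), 1:5)$statistic))
  expect_error(spearman(1:2, 1:2), ">= 3")
})

test_that("edge-class CGE curves find the planted gradient", {
  cfg <- synth_config(seed = 41)
  ds <- simulate_dataset(cfg)
  bil <- bilateral_pairs(ds$neurons)
  cge <- cge_matrix(ds$expression, "r_phi", bilateral_pairs = bil)
  deg <- degree_sequence(ds$connectome)
  kthr <- top16_threshold(deg)
  curve <- edge_class_cge_curve(cge, ds$connectome,
                                k_range = c(kthr - 4, kthr, kthr + 2))
  at_thr <- curve[curve$k == kthr, ]
  rich <- at_thr[at_thr$class == "rich", ]
  peri <- at_thr[at_thr$class == "peripheral", ]
  expect_gt(rich$median_cge, peri$median_cge)
  expect_true(rich$flag)
  # identical expression rows: every defined CGE is 1, no class stands out
  e1 <- ds$expression
  e1[] <- rep(e1[1, ], each = nrow(e1))
  cge1 <- cge_matrix(e1, "r_phi")
  curve1 <- edge_class_cge_curve(cge1, ds$connectome, k_range = kthr)
  expect_true(all(curve1$median_cge[curve1$n > 0] == 1))
  expect_false(any(curve1$flag))
})

test_that("pair-set comparisons reject overlap and detect the planted contrast", {
  cfg <- synth_config(seed = 43)
  ds <- simulate_dataset(cfg)
  bil <- bilateral_pairs(ds$neurons)
  cge <- cge_matrix(ds$expression, "r_phi", bilateral_pairs = bil)
  deg <- degree_sequence(ds$connectome)
  hubs <- label_hubs(deg, top16_threshold(deg))
  is_hub <- setNames(hubs$is_hub, hubs$neuron)
  cp <- connected_pairs(ds$connectome)
  rich <- is_hub[cp$a] & is_hub[cp$b]
  peri <- !is_hub[cp$a] & !is_hub[cp$b]
  res <- compare_pair_sets(cge, cbind(cp$a[rich], cp$b[rich]),
                           cbind(cp$a[peri], cp$b[peri]),
                           test = "ranksum", alternative = "greater")
  expect_lt(res$p, 0.05)
  expect_gt(res$median_a, res$median_b)
  expect_error(compare_pair_sets(cge, cbind(cp$a[rich], cp$b[rich]),
                                 cbind(cp$a[rich], cp$b[rich])), "overlap")
})

test_that("composition-matched nulls are calibrated and flag planted hub sets", {
  cfg <- synth_config(seed = 47)
  ds <- simulate_dataset(cfg)
  nt <- ds$neurons
  cge <- cge_matrix(ds$expression, "r_phi",
                    bilateral_pairs = bilateral_pairs(nt))
  # planted hubs have elevated within-set CGE against region-matched sets
  res <- composition_matched_null(cge, nt, ds$hubs, match_on = "region",
                                  n_perm = 2000, seed = 3)
  expect_lt(res$p, 0.01)
  # self-null: a random composition-matched set is not significant at the
  # same rate (single draw sanity check: p spread over (0, 1])
  lv <- setNames(nt$region, nt$neuron)
  comp <- table(lv[ds$hubs])
  rand_set <- nemacge:::with_seed(8, unlist(lapply(names(comp), function(r)
    sample(nt$neuron[nt$region == r], comp[[r]]))))
  res0 <- composition_matched_null(cge, nt, rand_set, match_on = "region",
                                   n_perm = 500, seed = 4)
  expect_gt(res0$p, 0.05)
  # unsatisfiable composition errors with the level name
  expect_error(composition_matched_null(cge, nt, ds$hubs,
                                        match_on = "region", n_perm = 10,
                                        seed = 1,
                                        composition = c(tail = 1000)),
               "tail")
  # match_on = NULL degenerates to simple same-size random sets
  res_free <- composition_matched_null(cge, nt, ds$hubs, match_on = NULL,
                                       n_perm = 500, seed = 5)
  expect_lt(res_free$p, 0.05)
  # determinism and add-one positivity
  r1 <- composition_matched_null(cge, nt, ds$hubs, match_on = "region",
                                 n_perm = 200, seed = 9)
  r2 <- composition_matched_null(cge, nt, ds$hubs, match_on = "region",
                                 n_perm = 200, seed = 9)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)
})
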