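test_that("degrees follow the bidirectional-gap convention on a toy graph", {
  cn <- toy_connectome()
  deg <- degree_sequence(cn)
  expect_equal(deg$k[deg$neuron == "A"], 1)    # out 1
  expect_equal(deg$k_out[deg$neuron == "A"], 1)
  expect_equal(deg$k[deg$neuron == "B"], 3)    # in: chem + gap; out: gap
  expect_equal(deg$k_in[deg$neuron == "B"], 2)
  expect_equal(deg$k[deg$neuron == "C"], 2)
  expect_equal(deg$k, deg$k_in + deg$k_out)
  expect_equal(sum(deg$k_in), sum(deg$k_out))
})

test_that("complete chemical digraph gives uniform degrees", {
  nodes <- c("a", "b", "c", "d")
  pairs <- expand.grid(pre = nodes, post = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$pre != pairs$post, ]
  cn <- connectome(nodes, chem = cbind(pairs, weight = 1))
  deg <- degree_sequence(cn)
  expect_true(all(deg$k == 6))
  expect_true(all(deg$k_in == 3) && all(deg$k_out == 3))
})

test_that("a pair with both mechanisms counts per mechanism in degrees but once as a pair", {
  cn <- connectome(c("A", "B"),
                   chem = data.frame(pre = "A", post = "B", weight = 2),
                   gap = data.frame(a = "A", b = "B", weight = 1))
  deg <- degree_sequence(cn)
  expect_equal(deg$k[deg$neuron == "A"], 3)  # chem out + gap in/out
  expect_equal(nrow(connected_pairs(cn)), 1)
})

test_that("loader validates inputs and reports counts; write/load round-trips", {
  dir <- withr::local_tempdir()
  nt <- data.frame(neuron = c("A", "B", "C"), x_um = c(0, 3, 0),
                   y_um = c(0, 4, 1), region = "head", types = "interneuron",
                   neurotransmitter = "acetylcholine", birth_time_min = 100,
                   bilateral_partner = "", command_interneuron = 0)
  write.table(nt, file.path(dir, "neurons.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ed <- data.frame(pre = c("A", "B"), post = c("B", "C"),
                   type = c("chem", "gap"), weight = c(2, 1))
  write.table(ed, file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cn <- load_connectome(file.path(dir, "edges.tsv"),
                        file.path(dir, "neurons.tsv"), quiet = TRUE)
  expect_equal(degree_sequence(cn)$k, degree_sequence(toy_connectome())$k)

  # round trip
  write_connectome(cn, file.path(dir, "e2.tsv"), file.path(dir, "n2.tsv"))
  cn2 <- load_connectome(file.path(dir, "e2.tsv"), file.path(dir, "n2.tsv"),
                         quiet = TRUE)
  expect_equal(cn2$chem, cn$chem)
  expect_equal(cn2$gap, cn$gap)

  # unknown neuron named in the error
  ed_bad <- rbind(ed, data.frame(pre = "A", post = "XXX", type = "chem",
                                 weight = 1))
  write.table(ed_bad, file.path(dir, "bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_connectome(file.path(dir, "bad.tsv"),
                               file.path(dir, "neurons.tsv"), quiet = TRUE),
               "XXX")

  # duplicate record
  ed_dup <- rbind(ed, ed[1, ])
  write.table(ed_dup, file.path(dir, "dup.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_connectome(file.path(dir, "dup.tsv"),
                               file.path(dir, "neurons.tsv"), quiet = TRUE),
               "duplicate")

  # empty edge file: zero degrees
  write.table(ed[0, ], file.path(dir, "empty.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cn0 <- load_connectome(file.path(dir, "empty.tsv"),
                         file.path(dir, "neurons.tsv"), quiet = TRUE)
  expect_true(all(degree_sequence(cn0)$k == 0))
})

test_that("hub labeling uses strict inequality and is monotone in the threshold", {
  cn <- toy_connectome()
  deg <- degree_sequence(cn)
  expect_equal(sum(label_hubs(deg, 2)$is_hub), 1)   # only B (k = 3)
  expect_equal(sum(label_hubs(deg, 3)$is_hub), 0)   # strict: k > 3 required
  expect_equal(sum(label_hubs(deg, max(deg$k))$is_hub), 0)
  expect_equal(sum(label_hubs(deg, -1)$is_hub), 3)
  counts <- sapply(0:4, function(k) sum(label_hubs(deg, k)$is_hub))
  expect_true(all(diff(counts) <= 0))
})

test_that("edge classification applies the hub rule and partitions all edges", {
  cn <- toy_connectome()
  hubs <- label_hubs(degree_sequence(cn), 2)  # B is the only hub
  cls <- classify_edges(cn, hubs)
  lab <- setNames(cls$class, paste(cls$pre, cls$post))
  expect_equal(unname(lab["A B"]), "feed-in")
  expect_equal(unname(lab["B C"]), "feed-out")
  expect_equal(unname(lab["C B"]), "feed-in")

  # partition invariant across thresholds
  cn2 <- random_connectome(15, 0.3, seed = 42)
  deg2 <- degree_sequence(cn2)
  n_edges <- nrow(directed_edges(cn2))
  for (k in c(0, 3, 6, 10, max(deg2$k))) {
    cls2 <- classify_edges(cn2, label_hubs(deg2, k))
    expect_equal(sum(attr(cls2, "class_counts")), n_edges)
  }
  expect_true(all(classify_edges(cn2, label_hubs(deg2, -1))$class == "rich"))
  expect_true(all(classify_edges(cn2, label_hubs(deg2, max(deg2$k)))$class ==
                    "peripheral"))
})

test_that("constructor rejects malformed connectomes", {
  expect_error(connectome(c("A", "B"),
                          chem = data.frame(pre = "A", post = "A", weight = 1)),
               "self-edges")
  expect_error(connectome(c("A", "B"),
                          chem = data.frame(pre = c("A", "A"),
                                            post = c("B", "B"),
                                            weight = 1)),
               "duplicate")
  expect_error(connectome(c("A", "A")), "duplicate")
})
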