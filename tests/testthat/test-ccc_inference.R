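# small trained model shared across inference tests
fx <- tiny_fixture()
mod <- train(fx$ds$expression, fx$Ac, fx$Ag, fast_hp(), seed = 4)

fake_net <- function(probs, cutoff = 0.5) {
  edges <- probs >= cutoff
  diag(edges) <- FALSE
  structure(list(probs = probs, edges = edges, cutoff = cutoff),
            class = "ccc_network")
}

test_that("network prediction is deterministic with cutoff semantics", {
  n1 <- predict_ccc_network(mod, fx$ds$expression, fx$Ac)
  n2 <- predict_ccc_network(mod, fx$ds$expression, fx$Ac)
  expect_identical(n1$probs, n2$probs)
  expect_true(all(n1$probs >= 0 & n1$probs <= 1))
  expect_false(any(diag(n1$edges)))

  hi <- predict_ccc_network(mod, fx$ds$expression, fx$Ac, cutoff = 1)
  expect_equal(sum(hi$edges), sum(hi$probs[row(hi$probs) !=
                                             col(hi$probs)] == 1))
  lo <- predict_ccc_network(mod, fx$ds$expression, fx$Ac, cutoff = 0)
  n <- nrow(lo$probs)
  expect_equal(sum(lo$edges), n * (n - 1))
  expect_error(predict_ccc_network(mod, fx$ds$expression[1:5, ], fx$Ac),
               "mismatch")
})

test_that("cell-type aggregation equals the brute-force pair mean", {
  # hand example: types A = {a1, a2}, B = {b1}
  probs <- matrix(0, 3, 3, dimnames = list(c("a1", "a2", "b1"),
                                           c("a1", "a2", "b1")))
  probs["a1", "b1"] <- 0.2; probs["a2", "b1"] <- 0.4
  lab <- cell_labels(c("A", "A", "B"), c("a1", "a2", "b1"))
  agg <- aggregate_by_cell_type(fake_net(probs), lab)
  expect_equal(agg$strength["A", "B"], 0.3)
  expect_equal(agg$strength["B", "B"], 0)  # single cell: zero pairs

  # constant field: every strength with at least one valid pair equals it
  cp <- matrix(0.7, 3, 3, dimnames = dimnames(probs))
  cs <- aggregate_by_cell_type(fake_net(cp), lab)$strength
  expect_true(all(abs(cs[cbind(c("A", "A", "B"), c("A", "B", "A"))] - 0.7)
                  < 1e-12))
  expect_equal(cs["B", "B"], 0)

  set.seed(6)
  n <- 17
  ids <- sprintf("c%d", 1:n)
  P <- matrix(runif(n * n), n, dimnames = list(ids, ids))
  labs <- cell_labels(sample(c("X", "Y", "Z"), n, TRUE), ids)
  agg2 <- aggregate_by_cell_type(fake_net(P), labs)
  expect_equal(agg2$strength, bf_aggregate(P, unclass(labs)),
               tolerance = 1e-12)

  # permuting cell order leaves the matrix unchanged
  perm <- sample(n)
  P2 <- P[perm, perm]
  agg3 <- aggregate_by_cell_type(fake_net(P2), labs)
  expect_equal(agg3$strength, agg2$strength, tolerance = 1e-12)
})

test_that("permutation p-values follow the percentile convention", {
  # strength driven entirely by the labels: observed A->B beats every
  # permuted arrangement, so p hits the floor 1/(n_perm + 1)
  n <- 20
  ids <- sprintf("c%d", 1:n)
  lab <- cell_labels(rep(c("A", "B"), each = 10), ids)
  probs <- matrix(0, n, n, dimnames = list(ids, ids))
  probs[1:10, 11:20] <- 1
  pt <- permutation_test(fake_net(probs), lab, n_perm = 99, seed = 2)
  expect_equal(pt$pvalue["A", "B"], 1 / 100)
  expect_true(all(pt$pvalue > 0 & pt$pvalue <= 1))
  pt2 <- permutation_test(fake_net(probs), lab, n_perm = 99, seed = 2)
  expect_identical(pt2$pvalue, pt$pvalue)
  expect_equal(pt$strength["A", "B"], 1)
})

test_that("LR impact ratios count edges and stay in [0, 1]", {
  # arithmetic on the counting helper through constructed networks
  ids <- sprintf("c%d", 1:4)
  lab <- cell_labels(c("S", "S", "R", "R"), ids)
  pf <- matrix(0, 4, 4, dimnames = list(ids, ids))
  pf[1:2, 3:4] <- 1  # E_full = 4
  expect_equal(orthoccc:::count_type_edges(fake_net(pf), lab, "S", "R"), 4)
  pp <- pf; pp[1, 3:4] <- 0  # E_pert = 2
  expect_equal(orthoccc:::count_type_edges(fake_net(pp), lab, "S", "R"), 2)
  expect_equal(max(0, (4 - 2) / 4), 0.5)

  # end-to-end on the trained fixture: deterministic and bounded
  edge <- c(fx$Ag$pair_index$ligand[1], fx$Ag$pair_index$receptor[1])
  types <- unique(unclass(fx$ds$labels))
  r1 <- lr_pair_impact(fx$ds$expression, fx$Ac, fx$Ag, edge,
                       types[1], types[2], fx$ds$labels,
                       fast_hp(epochs = 20L), seed = 4)
  r2 <- lr_pair_impact(fx$ds$expression, fx$Ac, fx$Ag, edge,
                       types[1], types[2], fx$ds$labels,
                       fast_hp(epochs = 20L), seed = 4)
  expect_identical(r1, r2)
  expect_gte(r1, 0); expect_lte(r1, 1)
  expect_error(lr_pair_impact(fx$ds$expression, fx$Ac, fx$Ag,
                              c("nope", "nah"), types[1], types[2],
                              fx$ds$labels), "not present")
})

test_that("LR ranking sorts by ratio with lexicographic tie-breaks", {
  tab <- data.frame(ligand = c("L3", "L1", "L2"),
                    receptor = c("R3", "R1", "R2"),
                    sender = "S", receiver = "R",
                    edge_reduction_ratio = c(0.9, 0.1, 0.5),
                    stringsAsFactors = FALSE)
  top <- rank_lr_pairs(tab, top_k = 2)
  expect_equal(top$edge_reduction_ratio, c(0.9, 0.5))
  expect_equal(top$rank, c(1L, 2L))

  ties <- data.frame(ligand = c("Lb", "La", "Lc"),
                     receptor = c("R", "R", "R"),
                     sender = "S", receiver = "R",
                     edge_reduction_ratio = c(0.4, 0.4, 0.4),
                     stringsAsFactors = FALSE)
  rt <- rank_lr_pairs(ties, top_k = 10)
  expect_equal(rt$ligand, c("La", "Lb", "Lc"))  # whole table returned
  expect_equal(rt$rank, c(1L, 1L, 1L))          # dense ranks share ties
})

test_that("spectral clustering separates planted blocks", {
  n <- 24
  ids <- sprintf("c%d", 1:n)
  block <- rep(1:2, each = n / 2)
  P <- matrix(0.02, n, n, dimnames = list(ids, ids))
  P[block == 1, block == 1] <- 0.9
  P[block == 2, block == 2] <- 0.9
  cl <- spectral_clusters(fake_net(P), k = 2, seed = 1)
  expect_equal(length(unique(cl)), 2L)
  # partition agreement, label-invariant
  expect_true(all(table(cl, block) %in% c(0L, n / 2)))
  expect_identical(spectral_clusters(fake_net(P), k = 2, seed = 1), cl)
  expect_identical(unname(spectral_clusters(fake_net(P), k = n)),
                   seq_len(n))
  expect_error(spectral_clusters(fake_net(P), k = n + 1), "exceed")
})

test_that("network edge lists round-trip through the writer", {
  net <- predict_ccc_network(mod, fx$ds$expression, fx$Ac)
  el <- network_edge_list(net)
  expect_true(all(el$weight >= net$cutoff))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(el, f)
  back <- read_edge_list(f)
  rownames(el) <- NULL
  expect_equal(back, el)
})
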