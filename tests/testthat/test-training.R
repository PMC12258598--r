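test_that("graph reconstruction loss matches scalar cross-entropy", {
  expect_equal(graph_reconstruction_loss(matrix(0.5), matrix(1)), log(2),
               tolerance = 1e-12)
  # perfect reconstruction: loss vanishes up to the clipping epsilon
  A <- rbind(c(0, 1), c(1, 0))
  expect_lt(graph_reconstruction_loss(A, A), 4 * -log(1 - 1e-7) + 1e-9)
  # p = 0.5 everywhere: loss independent of A when pos_weight = 1
  set.seed(1)
  A1 <- matrix(rbinom(16, 1, 0.5), 4)
  A2 <- matrix(rbinom(16, 1, 0.2), 4)
  half <- matrix(0.5, 4, 4)
  expect_equal(graph_reconstruction_loss(half, A1),
               graph_reconstruction_loss(half, A2))
  expect_equal(graph_reconstruction_loss(half, A1), log(2),
               tolerance = 1e-12)
  expect_error(graph_reconstruction_loss(matrix(1.2), matrix(1)),
               "outside")
})

test_that("expression loss is the per-entry squared Frobenius norm", {
  X <- rbind(c(1, 2), c(3, 4))
  expect_equal(expression_loss(X, X), 0)
  expect_equal(expression_loss(X, X * 0), 7.5)
  Xh <- X + matrix(c(0.1, -0.2, 0.3, 0), 2)
  expect_equal(expression_loss(3 * X, 3 * Xh), 9 * expression_loss(X, Xh),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    A <- matrix(rnorm(35), 5, 7); B <- matrix(rnorm(35), 5, 7)
    expect_equal(expression_loss(A, B), bf_expression_loss(A, B),
                 tolerance = 1e-10)
  }
})

test_that("similarity matrix is the cell-by-cell cosine with 0 convention", {
  I3 <- diag(3)
  expect_equal(similarity_matrix(I3, I3), diag(3))
  u <- c(1, 2, 3); v <- c(4, 5, 6)
  S <- similarity_matrix(cbind(u), cbind(v))
  expect_equal(round(S[1, 1], 4), 0.9746)
  expect_equal(S[1, 1], 32 / (sqrt(14) * sqrt(77)), tolerance = 1e-12)
  orth <- similarity_matrix(cbind(c(1, 0)), cbind(c(0, 1)))
  expect_equal(orth[1, 1], 0)
  withzero <- similarity_matrix(cbind(c(0, 0), c(1, 1)), cbind(c(1, 2), c(3, 4)))
  expect_equal(withzero[1, ], c(0, 0))
  set.seed(3)
  for (i in 1:10) {
    A <- matrix(rnorm(35), 5, 7); B <- matrix(rnorm(35), 5, 7)
    expect_equal(similarity_matrix(A, B), bf_similarity(A, B),
                 tolerance = 1e-10)
  }
})

test_that("orthogonal loss penalizes departure from the identity", {
  expect_equal(orthogonal_loss(diag(4)), 0)
  expect_equal(orthogonal_loss(matrix(1, 2, 2)), 0.5)
  set.seed(4)
  for (i in 1:10) {
    S <- matrix(runif(36, -1, 1), 6)
    expect_equal(orthogonal_loss(S), bf_orthogonal_loss(S),
                 tolerance = 1e-10)
    expect_lte(orthogonal_loss(S), 4)
  }
  # orthogonal nonzero columns of the same matrix give exactly zero
  M <- cbind(c(2, 0, 0), c(0, 0, 3))
  expect_equal(orthogonal_loss(similarity_matrix(M, M)), 0)
})

test_that("total loss is the additive minimization objective", {
  zero <- loss_breakdown(0, 0, 0, 0, 0, 0, 0)
  expect_equal(total_loss(zero), 0)
  parts <- loss_breakdown(0.3, 0.02, 1.5, 0.4, 0.01, 1.2, 0.25,
                          beta = 2, orth_weight = 0.5)
  expect_equal(total_loss(parts),
               (0.3 + 2 * 0.02 + 1.5) + (0.4 + 2 * 0.01 + 1.2) + 0.5 * 0.25)
  bumped <- parts; bumped$orth <- parts$orth + 1
  expect_equal(total_loss(bumped) - total_loss(parts), 0.5)
})

test_that("analytic gradients agree with finite differences", {
  fx <- tiny_fixture(n_cells = 10L, n_genes = 8L, n_lr_pairs = 3L)
  hp <- default_hyperparams(hidden_dim = 6L, latent_dim = 4L, epochs = 1L)
  X <- unclass(fx$ds$expression)
  Ag <- fx$Ag$adjacency; Ac <- fx$Ac$adjacency
  An_g <- normalize_adjacency(Ag); An_c <- normalize_adjacency(Ac)
  data <- list(X = X, A_g = Ag, A_c = Ac, An_g = An_g, An_c = An_c,
               tAn_g = t(An_g), tAn_c = t(An_c),
               T0_g = An_g %*% X, T0_c = An_c %*% t(X),
               wts_g = orthoccc:::bce_weights(Ag),
               wts_c = orthoccc:::bce_weights(Ac))
  set.seed(1)
  prm <- orthoccc:::init_model_params(nrow(X), ncol(X), hp)
  d <- hp$latent_dim
  eps_g <- matrix(rnorm(nrow(X) * d), nrow(X), d)
  eps_c <- matrix(rnorm(ncol(X) * d), ncol(X), d)
  fwd <- orthoccc:::forward_total(prm, data, eps_g, eps_c, hp)
  grads <- orthoccc:::backward_total(fwd, prm, data, hp)
  h <- 1e-5
  set.seed(42)
  for (ae in c("gene", "cell")) {
    for (w in names(prm[[ae]])) {
      W <- prm[[ae]][[w]]
      for (i in sample(length(W), min(6L, length(W)))) {
        p2 <- prm; p2[[ae]][[w]][i] <- W[i] + h
        f1 <- orthoccc:::forward_total(p2, data, eps_g, eps_c, hp)$total
        p2[[ae]][[w]][i] <- W[i] - h
        f0 <- orthoccc:::forward_total(p2, data, eps_g, eps_c, hp)$total
        num <- (f1 - f0) / (2 * h)
        ana <- grads[[ae]][[w]][i]
        expect_lt(abs(num - ana) / max(1, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("training is deterministic and reduces the loss", {
  fx <- tiny_fixture()
  hp <- fast_hp(epochs = 60L)
  m1 <- train(fx$ds$expression, fx$Ac, fx$Ag, hp, seed = 3)
  m2 <- train(fx$ds$expression, fx$Ac, fx$Ag, hp, seed = 3)
  expect_identical(m1$gene, m2$gene)
  expect_identical(m1$cell, m2$cell)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_equal(nrow(m1$loss_history), 60L)
  expect_lt(m1$loss_history$total[60], m1$loss_history$total[1])
  expect_true(all(is.finite(as.matrix(m1$loss_history))))
})

test_that("zero coupling weight decouples the two autoencoders", {
  fx <- tiny_fixture()
  hp <- fast_hp(epochs = 25L, orth_weight = 0)
  m1 <- train(fx$ds$expression, fx$Ac, fx$Ag, hp, seed = 9)
  # scramble the spatial arrangement: different cell graph, same gene graph
  xy <- unclass(fx$ds$coords)
  set.seed(99)
  co2 <- spatial_coords(xy[sample(nrow(xy)), ], cell_ids = rownames(xy))
  Ac2 <- build_spatial_graph(co2, fx$Ac$threshold_used)
  m2 <- train(fx$ds$expression, Ac2, fx$Ag, hp, seed = 9)
  expect_identical(m1$gene, m2$gene)
  expect_false(identical(m1$cell, m2$cell))
})

test_that("divergence aborts with a diagnostic naming the component", {
  fx <- tiny_fixture(n_cells = 12L, n_genes = 8L, n_lr_pairs = 3L)
  hp <- fast_hp(epochs = 200L, lr = 1e4)
  expect_error(train(fx$ds$expression, fx$Ac, fx$Ag, hp, seed = 1),
               "non-finite loss component")
})

test_that("model checkpoints round-trip through save/load", {
  fx <- tiny_fixture()
  m <- train(fx$ds$expression, fx$Ac, fx$Ag, fast_hp(epochs = 5L), seed = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_identical(load_model(f), m)
})
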