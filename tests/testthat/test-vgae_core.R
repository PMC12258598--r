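test_that("adjacency normalization matches the out-degree form", {
  expect_equal(normalize_adjacency(matrix(0, 3, 3)), diag(3))
  A <- rbind(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0))
  expect_equal(normalize_adjacency(A),
               rbind(c(1, 1, 1) / 3, c(0, 1, 1) / 2, c(0, 0, 1)))
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:15, 1)
    A <- matrix(rbinom(n * n, 1, 0.3), n); diag(A) <- 0
    expect_equal(rowSums(normalize_adjacency(A)), rep(1, n),
                 tolerance = 1e-9)
  }
  expect_error(normalize_adjacency(matrix(0, 2, 3)), "square")
})

test_that("encoder computes the two-layer GCN with shared first layer", {
  # N = 1: A = 0 so A_norm = 1; hidden = ReLU(1*1*2) = 2; mu = 2*3 = 6
  prm <- structure(list(W0 = matrix(2), W1_mu = matrix(3),
                        W1_sigma = matrix(-1)), class = "encoder_params")
  out <- encode(matrix(1), matrix(1), prm)
  expect_equal(out$mu[1, 1], 6)
  expect_equal(out$log_sigma[1, 1], -2)

  # zero features give zero outputs regardless of weights
  set.seed(2)
  p2 <- init_encoder_params(4, 8, 6)
  A <- matrix(rbinom(25, 1, 0.4), 5); diag(A) <- 0
  z <- encode(normalize_adjacency(A), matrix(0, 5, 4), p2)
  expect_true(all(z$mu == 0) && all(z$log_sigma == 0))
  expect_error(encode(normalize_adjacency(A), matrix(0, 4, 4), p2), "align")
})

test_that("encode -> decode_graph is node-permutation equivariant", {
  set.seed(13)
  n <- 9
  A <- matrix(rbinom(n * n, 1, 0.35), n); diag(A) <- 0
  X <- matrix(rnorm(n * 5), n, 5)
  prm <- init_encoder_params(5, 7, 4)
  P <- decode_graph(encode(normalize_adjacency(A), X, prm)$mu)
  perm <- sample(n)
  P2 <- decode_graph(encode(normalize_adjacency(A[perm, perm]),
                            X[perm, , drop = FALSE], prm)$mu)
  expect_equal(P2, P[perm, perm], tolerance = 1e-12)
})

test_that("posterior sampling is deterministic, exact in eval mode", {
  enc <- structure(list(mu = matrix(1:6 / 2, 3, 2),
                        log_sigma = matrix(-0.3, 3, 2)),
                   class = "encoder_output")
  expect_identical(sample_latent(enc, eval = TRUE), enc$mu)
  expect_identical(sample_latent(enc, seed = 4), sample_latent(enc, seed = 4))
  # sigma -> 0 limit collapses to the mean
  enc0 <- enc; enc0$log_sigma <- matrix(-1e3, 3, 2)
  expect_equal(sample_latent(enc0, seed = 1), enc$mu, tolerance = 1e-12)
  # CLT: per-coordinate mean of standard normal draws is near zero
  encN <- structure(list(mu = matrix(0, 10000, 2),
                         log_sigma = matrix(0, 10000, 2)),
                    class = "encoder_output")
  zm <- colMeans(sample_latent(encN, seed = 2))
  expect_true(all(abs(zm) < 0.05))
  enc_odd <- structure(list(mu = matrix(0, 2, 3), log_sigma = matrix(0, 2, 3)),
                       class = "encoder_output")
  expect_error(sample_latent(enc_odd), "even")
})

test_that("directed decoder uses source/target halves and is asymmetric", {
  expect_equal(decode_graph(matrix(0, 4, 6)), matrix(0.5, 4, 4))
  Z <- rbind(c(2, 0, 0, 0), c(0, 0, 1, 0))
  P <- decode_graph(Z)
  expect_equal(P[1, 2], plogis(2), tolerance = 1e-12)   # 0.8808 at 4 d.p.
  expect_equal(round(P[1, 2], 4), 0.8808)
  expect_equal(P[2, 1], 0.5)
  # negating the source half maps p to 1 - p
  Zn <- Z; Zn[, 1:2] <- -Zn[, 1:2]
  expect_equal(decode_graph(Zn), 1 - P, tolerance = 1e-12)
  expect_error(decode_graph(matrix(0, 2, 3)), "even")
})

test_that("decode_graph matches the brute-force double loop", {
  set.seed(4)
  for (n in c(3, 11, 20)) {
    Z <- matrix(rnorm(n * 8), n, 8)
    expect_equal(decode_graph(Z), bf_decode_graph(Z), tolerance = 1e-12)
  }
})

test_that("dense expression decoder computes ReLU-linear layers", {
  dec <- structure(list(V0 = matrix(1), b0 = 0, V1 = matrix(1), b1 = 0),
                   class = "dense_decoder")
  expect_equal(decode_expression(matrix(2), dec)[1, 1], 2)
  expect_equal(decode_expression(matrix(-2), dec)[1, 1], 0)  # ReLU gate
  set.seed(6)
  dz <- init_dense_decoder(4, 6, 9)
  dz0 <- dz; dz0$V1 <- dz$V1 * 0; dz0$b1 <- dz$b1 * 0
  Z <- matrix(rnorm(12), 3, 4)
  expect_true(all(decode_expression(Z, dz0) == 0))
  expect_equal(dim(decode_expression(Z, dz)), c(3L, 9L))
})

test_that("KL divergence matches closed form and a Monte-Carlo estimate", {
  zero <- structure(list(mu = matrix(0, 2, 4), log_sigma = matrix(0, 2, 4)),
                    class = "encoder_output")
  expect_equal(kl_divergence(zero), 0)
  one <- structure(list(mu = matrix(1), log_sigma = matrix(0)),
                   class = "encoder_output")
  expect_equal(kl_divergence(one), 0.5)
  # strictly increasing in |mu| at fixed sigma
  kls <- vapply(c(0, 0.5, 1, 2), function(m)
    kl_divergence(structure(list(mu = matrix(m), log_sigma = matrix(0)),
                            class = "encoder_output")), numeric(1))
  expect_true(all(diff(kls) > 0))

  # Monte-Carlo cross-check: E_q[log q - log p] over 1e5 samples
  set.seed(10)
  mu <- rnorm(3); ls <- rnorm(3, 0, 0.4)
  enc <- structure(list(mu = matrix(mu, 1), log_sigma = matrix(ls, 1)),
                   class = "encoder_output")
  B <- 1e5
  draws <- matrix(rnorm(B * 3), B, 3, byrow = FALSE)
  z <- sweep(sweep(draws, 2, exp(ls), "*"), 2, mu, "+")
  lq <- sapply(1:3, function(k) dnorm(z[, k], mu[k], exp(ls[k]), log = TRUE))
  lp <- sapply(1:3, function(k) dnorm(z[, k], 0, 1, log = TRUE))
  diffs <- rowSums(lq - lp)
  se <- sd(diffs) / sqrt(B)
  expect_lt(abs(kl_divergence(enc) - mean(diffs)), 3 * se)
})
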