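# Joint training of the two coupled autoencoders.
#
# The objective (minimization form) is
#   L = (L_Ag + beta * KL_g + L_Xg) + (L_Ac + beta * KL_c + L_Xc) + L_orth
# where L_A* are weighted Bernoulli cross-entropies on the reconstructed
# adjacencies (the negative expected log-likelihood part of the ELBO), KL_*
# the KL divergences at objective scale (per-node KL / N), L_X* the
# per-entry mean squared expression reconstruction errors, and L_orth drives
# the cell-by-cell cosine-similarity matrix between the two reconstructed
# expression matrices toward the identity. Gradients of every term are
# analytic (see the backward pass below) and optimized with Adam.

#' Weighted graph reconstruction cross-entropy
#'
#' `norm * mean` over all ordered node pairs of the Bernoulli cross-entropy
#' between predicted edge probabilities and the binary adjacency, positives
#' weighted by `pos_weight`. With `pos_weight = norm = 1` this equals
#' `-(1/N^2) * sum(log p(A_ij | z))`. Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param probs N x N matrix of edge probabilities in `[0, 1]`.
#' @param A binary adjacency of the same shape.
#' @param pos_weight weight on positive (edge) terms; sparse graphs use
#'   `(N^2 - E) / E`.
#' @param norm overall scale; sparse graphs use `N^2 / (2 (N^2 - E))`.
#' @return a single nonnegative number.
#' @export
graph_reconstruction_loss <- function(probs, A, pos_weight = 1, norm = 1) {
  if (!all(dim(probs) == dim(A))) stop("shape mismatch")
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities outside [0, 1]")
  eps <- 1e-7
  p <- pmin(pmax(probs, eps), 1 - eps)
  norm * mean(-pos_weight * A * log(p) - (1 - A) * log(1 - p))
}

#' Mean squared expression reconstruction error
#'
#' Squared Frobenius norm of `X - X_hat` divided by the number of entries
#' `m * n`.
#'
#' @param X observed genes x cells matrix.
#' @param X_hat reconstructed matrix of the same shape.
#' @return a single nonnegative number.
#' @export
expression_loss <- function(X, X_hat) {
  X <- unclass(X); X_hat <- unclass(X_hat)
  if (!all(dim(X) == dim(X_hat))) stop("shape mismatch")
  mean((X - X_hat)^2)
}

#' Cosine similarity matrix between two reconstructed expression matrices
#'
#' `S[i, j]` is the cosine similarity between cell i's reconstructed profile
#' from the cell-level decoder and cell j's profile from the gene-level
#' decoder; both inputs must be in canonical genes x cells orientation.
#' Zero-norm columns yield similarity 0 by convention.
#'
#' @param X_hat_c cell-level reconstruction, genes x cells.
#' @param X_hat_g gene-level reconstruction, genes x cells.
#' @return an n x n matrix with entries in `[-1, 1]`.
#' @export
similarity_matrix <- function(X_hat_c, X_hat_g) {
  X_hat_c <- unclass(X_hat_c); X_hat_g <- unclass(X_hat_g)
  if (!all(dim(X_hat_c) == dim(X_hat_g))) stop("shape mismatch")
  nc <- normalize_columns(X_hat_c)
  ng <- normalize_columns(X_hat_g)
  crossprod(nc$M, ng$M)
}

normalize_columns <- function(M) {
  nrm <- sqrt(colSums(M^2))
  safe <- ifelse(nrm == 0, 1, nrm)
  Mn <- sweep(M, 2, safe, "/")
  Mn[, nrm == 0] <- 0
  list(M = Mn, norm = nrm, safe = safe)
}

#' Orthogonal coupling loss
#'
#' Mean over all `n^2` entries of `(S - I)^2`: the penalty that forces each
#' cell's two reconstructions to agree (diagonal toward 1) while keeping
#' different cells' reconstructions dissimilar (off-diagonal toward 0).
#'
#' @param S a square cosine-similarity matrix.
#' @return a single nonnegative number (at most 4 for valid cosines).
#' @export
orthogonal_loss <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("S must be square")
  mean((S - diag(nrow(S)))^2)
}

#' Assemble a loss breakdown record
#'
#' @param graph_recon_g,graph_recon_c weighted graph reconstruction losses.
#' @param kl_g,kl_c per-node KL divergences.
#' @param expr_g,expr_c expression reconstruction losses.
#' @param orth orthogonal coupling loss.
#' @param beta KL weight.
#' @param orth_weight weight on the coupling loss.
#' @return a list of class `loss_breakdown`.
#' @export
loss_breakdown <- function(graph_recon_g, kl_g, expr_g,
                           graph_recon_c, kl_c, expr_c,
                           orth, beta = 1, orth_weight = 1) {
  structure(list(graph_recon_g = graph_recon_g, kl_g = kl_g, expr_g = expr_g,
                 graph_recon_c = graph_recon_c, kl_c = kl_c, expr_c = expr_c,
                 orth = orth, beta = beta, orth_weight = orth_weight),
            class = "loss_breakdown")
}

#' Total training objective from a loss breakdown
#'
#' `(graph_recon_g + beta * kl_g + expr_g) + (graph_recon_c + beta * kl_c +
#' expr_c) + orth_weight * orth` — the minimization form of the summed
#' objective (negated ELBOs plus reconstruction errors plus the coupling
#' penalty).
#'
#' @param parts a [loss_breakdown].
#' @return a single number.
#' @export
total_loss <- function(parts) {
  with(parts, (graph_recon_g + beta * kl_g + expr_g) +
         (graph_recon_c + beta * kl_c + expr_c) + orth_weight * orth)
}

#' Default training hyperparameters
#'
#' @param hidden_dim encoder/decoder hidden width (default 32).
#' @param latent_dim even latent dimension `d` (default 16).
#' @param epochs training epochs (default 200).
#' @param lr Adam learning rate (default 0.01).
#' @param beta KL weight (default 1).
#' @param orth_weight coupling-loss weight (default 1; 0 fully decouples
#'   the two autoencoders).
#' @param pos_weight,norm graph-loss class weights; `NULL` (default) means
#'   the standard sparse-graph values `(N^2 - E)/E` and `N^2 / (2(N^2 - E))`
#'   computed per graph.
#' @return a list of class `ccc_hyperparams`.
#' @export
default_hyperparams <- function(hidden_dim = 32L, latent_dim = 16L,
                                epochs = 200L, lr = 0.01, beta = 1,
                                orth_weight = 1, pos_weight = NULL,
                                norm = NULL) {
  if (latent_dim %% 2L != 0L) stop("latent_dim must be even")
  structure(list(hidden_dim = as.integer(hidden_dim),
                 latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs), lr = lr, beta = beta,
                 orth_weight = orth_weight, pos_weight = pos_weight,
                 norm = norm),
            class = "ccc_hyperparams")
}

# --- internal forward/backward machinery -----------------------------------

bce_weights <- function(A, pos_weight = NULL, norm = NULL) {
  N <- nrow(A); E <- sum(A)
  if (E == 0 || E == N * N) {
    pw <- 1; nr <- 1  # degenerate graph: unweighted loss
  } else {
    pw <- (N^2 - E) / E
    nr <- N^2 / (2 * (N^2 - E))
  }
  list(pos_weight = if (is.null(pos_weight)) pw else pos_weight,
       norm = if (is.null(norm)) nr else norm)
}

# one autoencoder's forward pass; T0 = A_norm %*% features is precomputed
ae_forward <- function(T0, An, A, prm, pre_w, eps, beta, wts) {
  pre <- T0 %*% prm$W0
  H <- pmax(pre, 0)
  AH <- An %*% H
  mu <- AH %*% prm$W1_mu
  ls <- AH %*% prm$W1_sigma
  sigma <- exp(ls)
  Z <- mu + sigma * eps
  d <- ncol(Z); h <- d %/% 2L
  Zs <- Z[, seq_len(h), drop = FALSE]
  Zt <- Z[, h + seq_len(h), drop = FALSE]
  M <- Zs %*% t(Zt)
  P <- stats::plogis(M)
  Hd_pre <- sweep(Z %*% prm$V0, 2, prm$b0, "+")
  Hd <- pmax(Hd_pre, 0)
  Xhat <- sweep(Hd %*% prm$V1, 2, prm$b1, "+")
  N <- nrow(A)
  # KL as it enters the objective: the per-node KL divided by N again, so
  # it is commensurate with the per-entry-normalized graph term (the
  # scaling used by standard VGAE implementations; a per-node KL overwhelms
  # the edge gradients and collapses the posterior)
  kl <- 0.5 * sum(mu^2 + sigma^2 - 1 - 2 * ls) / N^2
  # logit-space cross-entropy: identical to graph_reconstruction_loss up to
  # its probability clipping, but smooth, so the analytic gradient is exact
  # even for saturated logits
  bce <- wts$norm * mean(-wts$pos_weight * A * stats::plogis(M, log.p = TRUE) -
                           (1 - A) * stats::plogis(-M, log.p = TRUE))
  list(pre = pre, H = H, AH = AH, mu = mu, ls = ls, sigma = sigma, Z = Z,
       Zs = Zs, Zt = Zt, P = P, Hd_pre = Hd_pre, Hd = Hd, Xhat = Xhat,
       kl = kl, bce = bce, N = N, h = h)
}

# backward for one autoencoder; gX is the gradient w.r.t. its node-major
# reconstruction (expression + coupling contributions already summed)
ae_backward <- function(fw, gX, T0, tAn, A, prm, beta, wts) {
  N <- fw$N
  gM <- (wts$norm / N^2) *
    (-wts$pos_weight * A * (1 - fw$P) + (1 - A) * fw$P)
  gZs <- gM %*% fw$Zt
  gZt <- crossprod(gM, fw$Zs)
  gV1 <- crossprod(fw$Hd, gX)
  gb1 <- colSums(gX)
  gHd <- gX %*% t(prm$V1)
  gHdp <- gHd * (fw$Hd_pre > 0)
  gV0 <- crossprod(fw$Z, gHdp)
  gb0 <- colSums(gHdp)
  gZ <- cbind(gZs, gZt) + gHdp %*% t(prm$V0)
  eps <- (fw$Z - fw$mu) / fw$sigma
  gmu <- gZ + beta * fw$mu / N^2
  gls <- gZ * eps * fw$sigma + beta * (fw$sigma^2 - 1) / N^2
  gW1mu <- crossprod(fw$AH, gmu)
  gW1sig <- crossprod(fw$AH, gls)
  gAH <- gmu %*% t(prm$W1_mu) + gls %*% t(prm$W1_sigma)
  gH <- tAn %*% gAH
  gpre <- gH * (fw$pre > 0)
  gW0 <- crossprod(T0, gpre)
  list(W0 = gW0, W1_mu = gW1mu, W1_sigma = gW1sig,
       V0 = gV0, b0 = gb0, V1 = gV1, b1 = gb1)
}

# gradient of the (weighted) orthogonal loss w.r.t. both canonical
# reconstructions; U = cell-level columns, V = gene-level columns
orth_grads <- function(U, V, weight) {
  n <- ncol(U)
  nu <- normalize_columns(U)
  nv <- normalize_columns(V)
  S <- crossprod(nu$M, nv$M)
  G <- weight * 2 * (S - diag(n)) / n^2
  dU <- sweep(nv$M %*% t(G) - sweep(nu$M, 2, rowSums(G * S), "*"),
              2, nu$safe, "/")
  dU[, nu$norm == 0] <- 0
  dV <- sweep(nu$M %*% G - sweep(nv$M, 2, colSums(G * S), "*"),
              2, nv$safe, "/")
  dV[, nv$norm == 0] <- 0
  list(S = S, dU = dU, dV = dV, loss = mean((S - diag(n))^2))
}

# full forward pass over both autoencoders plus coupling; eps fixed so the
# same function serves finite-difference gradient checks
forward_total <- function(prm, data, eps_g, eps_c, hp) {
  fg <- ae_forward(data$T0_g, data$An_g, data$A_g, prm$gene, NULL, eps_g,
                   hp$beta, data$wts_g)
  fc <- ae_forward(data$T0_c, data$An_c, data$A_c, prm$cell, NULL, eps_c,
                   hp$beta, data$wts_c)
  Xg_hat <- fg$Xhat          # genes x cells already
  Xc_can <- t(fc$Xhat)       # cells-major -> genes x cells
  og <- orth_grads(Xc_can, Xg_hat, hp$orth_weight)
  parts <- loss_breakdown(
    graph_recon_g = fg$bce, kl_g = fg$kl,
    expr_g = expression_loss(data$X, Xg_hat),
    graph_recon_c = fc$bce, kl_c = fc$kl,
    expr_c = expression_loss(data$X, Xc_can),
    orth = og$loss, beta = hp$beta, orth_weight = hp$orth_weight)
  list(fg = fg, fc = fc, og = og, Xg_hat = Xg_hat, Xc_can = Xc_can,
       parts = parts, total = total_loss(parts))
}

backward_total <- function(fwd, prm, data, hp) {
  mn <- length(data$X)
  gXg <- 2 * (fwd$Xg_hat - data$X) / mn + fwd$og$dV
  gXc_can <- 2 * (fwd$Xc_can - data$X) / mn + fwd$og$dU
  list(gene = ae_backward(fwd$fg, gXg, data$T0_g, data$tAn_g, data$A_g,
                          prm$gene, hp$beta, data$wts_g),
       cell = ae_backward(fwd$fc, t(gXc_can), data$T0_c, data$tAn_c,
                          data$A_c, prm$cell, hp$beta, data$wts_c))
}

adam_init <- function(prm) {
  rapply(prm, function(w) w * 0, how = "replace")
}

adam_step <- function(prm, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (ae in names(prm)) {
    for (w in names(prm[[ae]])) {
      g <- grads[[ae]][[w]]
      state$m[[ae]][[w]] <- b1 * state$m[[ae]][[w]] + (1 - b1) * g
      state$v[[ae]][[w]] <- b2 * state$v[[ae]][[w]] + (1 - b2) * g^2
      mhat <- state$m[[ae]][[w]] / (1 - b1^t)
      vhat <- state$v[[ae]][[w]] / (1 - b2^t)
      prm[[ae]][[w]] <- prm[[ae]][[w]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(prm = prm, state = state)
}

adjacency_of <- function(g) {
  if (is.list(g) && !is.null(g$adjacency)) g$adjacency else as.matrix(g)
}

init_model_params <- function(m, n, hp) {
  # fixed draw order so determinism and the decoupling property hold
  g_enc <- init_encoder_params(n, hp$hidden_dim, hp$latent_dim)
  g_dec <- init_dense_decoder(hp$latent_dim, hp$hidden_dim, n)
  c_enc <- init_encoder_params(m, hp$hidden_dim, hp$latent_dim)
  c_dec <- init_dense_decoder(hp$latent_dim, hp$hidden_dim, m)
  list(gene = c(unclass(g_enc), unclass(g_dec)),
       cell = c(unclass(c_enc), unclass(c_dec)))
}

#' Train the coupled autoencoders
#'
#' Jointly optimizes the gene-level autoencoder (over the directed
#' ligand-receptor graph, features = expression rows) and the cell-level
#' autoencoder (over the spatial graph, features = expression columns) on
#' the total objective with Adam. One posterior sample is drawn per
#' autoencoder per epoch; everything is deterministic given `seed`.
#'
#' @param expr an [expression_matrix] (m genes x n cells).
#' @param A_c a [build_spatial_graph()] result (or bare n x n adjacency).
#' @param A_g a [build_gene_graph()] result (or bare m x m adjacency).
#' @param hyperparams a [default_hyperparams()] list.
#' @param seed integer seed controlling initialization and posterior
#'   sampling.
#' @param verbose print the loss every 50 epochs.
#' @return a list of class `trained_model` with per-autoencoder `enc`
#'   ([init_encoder_params()]-shaped) and `dec`
#'   ([init_dense_decoder()]-shaped) weights, the resolved `hyperparams`,
#'   a per-epoch `loss_history` data.frame and the `seed`.
#' @export
train <- function(expr, A_c, A_g, hyperparams = default_hyperparams(),
                  seed = 1L, verbose = FALSE) {
  hp <- hyperparams
  X <- unclass(expr)
  Ac <- adjacency_of(A_c)
  Ag <- adjacency_of(A_g)
  m <- nrow(X); n <- ncol(X)
  if (nrow(Ac) != n) stop("cell graph size does not match expression")
  if (nrow(Ag) != m) stop("gene graph size does not match expression")
  An_g <- normalize_adjacency(Ag)
  An_c <- normalize_adjacency(Ac)
  data <- list(X = X, A_g = Ag, A_c = Ac, An_g = An_g, An_c = An_c,
               tAn_g = t(An_g), tAn_c = t(An_c),
               T0_g = An_g %*% X, T0_c = An_c %*% t(X),
               wts_g = bce_weights(Ag, hp$pos_weight, hp$norm),
               wts_c = bce_weights(Ac, hp$pos_weight, hp$norm))
  set.seed(seed)
  prm <- init_model_params(m, n, hp)
  state <- list(m = adam_init(prm), v = adam_init(prm))
  d <- hp$latent_dim
  hist <- vector("list", hp$epochs)
  for (ep in seq_len(hp$epochs)) {
    eps_g <- matrix(rnorm(m * d), m, d)
    eps_c <- matrix(rnorm(n * d), n, d)
    fwd <- forward_total(prm, data, eps_g, eps_c, hp)
    p <- fwd$parts
    vals <- c(graph_recon_g = p$graph_recon_g, kl_g = p$kl_g,
              expr_g = p$expr_g, graph_recon_c = p$graph_recon_c,
              kl_c = p$kl_c, expr_c = p$expr_c, orth = p$orth,
              total = fwd$total)
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop("training diverged: non-finite loss component '",
           names(vals)[bad[1]], "' at epoch ", ep)
    hist[[ep]] <- vals
    grads <- backward_total(fwd, prm, data, hp)
    upd <- adam_step(prm, grads, state, hp$lr, ep)
    prm <- upd$prm; state <- upd$state
    if (verbose && (ep %% 50L == 0L || ep == 1L))
      message(sprintf("epoch %d: total %.4f", ep, fwd$total))
  }
  loss_history <- as.data.frame(do.call(rbind, hist))
  loss_history$epoch <- seq_len(hp$epochs)
  split_params <- function(p) {
    list(enc = structure(p[c("W0", "W1_mu", "W1_sigma")],
                         class = "encoder_params"),
         dec = structure(p[c("V0", "b0", "V1", "b1")],
                         class = "dense_decoder"))
  }
  structure(list(gene = split_params(prm$gene),
                 cell = split_params(prm$cell),
                 hyperparams = hp,
                 wts_g = data$wts_g, wts_c = data$wts_c,
                 loss_history = loss_history,
                 dims = list(m = m, n = n),
                 gene_ids = rownames(X), cell_ids = colnames(X),
                 seed = seed),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  lh <- x$loss_history
  cat(sprintf(paste0(
    "trained_model: %d genes x %d cells, d=%d, %d epochs, ",
    "total loss %.4f -> %.4f\n"),
    x$dims$m, x$dims$n, x$hyperparams$latent_dim, nrow(lh),
    lh$total[1], lh$total[nrow(lh)]))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' Thin wrappers around [saveRDS()]/[readRDS()] for run-time checkpoints.
#' @param model a `trained_model`.
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "trained_model")) stop("not a trained_model checkpoint")
  m
}
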