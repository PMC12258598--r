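# Independent brute-force oracles (explicit loops, no shared code with the
# implementation) plus small fixture builders used across test files.

bf_average_precision <- function(scores, reference) {
  ord <- order(-scores)
  rel <- as.numeric(reference)[ord]
  tp <- 0; ap <- 0
  for (i in seq_along(rel)) {
    if (rel[i] == 1) {
      tp <- tp + 1
      ap <- ap + tp / i
    }
  }
  ap / sum(rel)
}

bf_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

bf_expression_loss <- function(X, Xh) {
  s <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X)))
    s <- s + (X[i, j] - Xh[i, j])^2
  s / (nrow(X) * ncol(X))
}

bf_similarity <- function(Xc, Xg) {
  n <- ncol(Xc)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- Xc[, i]; v <- Xg[, j]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    S[i, j] <- if (nu == 0 || nv == 0) 0 else sum(u * v) / (nu * nv)
  }
  S
}

bf_orthogonal_loss <- function(S) {
  n <- nrow(S)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + (S[i, j] - (i == j))^2
  s / n^2
}

bf_aggregate <- function(probs, lab) {
  types <- sort(unique(lab))
  K <- length(types)
  out <- matrix(0, K, K, dimnames = list(types, types))
  for (k in seq_len(K)) for (l in seq_len(K)) {
    tot <- 0; cnt <- 0
    for (i in which(lab == types[k])) for (j in which(lab == types[l])) {
      if (i == j) next
      tot <- tot + probs[i, j]; cnt <- cnt + 1
    }
    out[k, l] <- if (cnt == 0) 0 else tot / cnt
  }
  out
}

bf_decode_graph <- function(Z) {
  n <- nrow(Z); d <- ncol(Z); h <- d / 2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    P[i, j] <- 1 / (1 + exp(-sum(Z[i, 1:h] * Z[j, h + 1:h])))
  P
}

# a small trainable fixture shared by training/inference tests
tiny_fixture <- function(n_cells = 30L, n_genes = 12L, n_types = 2L,
                         n_lr_pairs = 4L, seed = 5L) {
  ds <- generate_dataset(synth_params(
    n_cells = n_cells, n_genes = n_genes, n_types = n_types,
    n_lr_pairs = n_lr_pairs, neighbor_radius = 300, seed = seed))
  thr <- select_distance_threshold(ds$coords)
  list(ds = ds,
       Ac = build_spatial_graph(ds$coords, thr),
       Ag = build_gene_graph(ds$lr_db, ds$expression))
}

fast_hp <- function(epochs = 60L, ...) {
  default_hyperparams(hidden_dim = 16L, latent_dim = 8L, epochs = epochs, ...)
}
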