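# Variational directed graph autoencoder primitives.
#
# Encoder: two-layer directed GCN, GCN(A, X) = Ã ReLU(Ã X W0) W1 with
# Ã = D_out^{-1}(A + I), the mean and log-std heads sharing W0.
# Graph decoder: p(Â_ij = 1 | z_i, z_j) = sigmoid(<z_i^(s), z_j^(t)>) with
# the first d/2 latent dimensions acting as the source (sender) half and the
# last d/2 as the target (receiver) half, so Â is generally asymmetric even
# when A is symmetric — this is how an undirected spatial graph is turned
# into a directed communication network.
# Expression decoder: two-layer dense net, ReLU hidden, linear output.

#' Row-normalize an adjacency matrix with self-loops
#'
#' Returns `D_out^{-1} (A + I)` where `D_out` is the diagonal out-degree
#' matrix of `A + I`; the self-loop guarantees every out-degree is at least
#' one, so every row sums to exactly 1.
#'
#' @param A square binary adjacency matrix (directed or undirected).
#' @return a row-stochastic matrix of the same shape.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  Ap <- A + diag(nrow(A))
  Ap / rowSums(Ap)
}

#' Initialize encoder parameters
#'
#' Glorot-uniform initialization; the first-layer weight `W0` is shared
#' between the mean and log-std heads.
#'
#' @param input_dim number of node features.
#' @param hidden_dim hidden layer width (default 32).
#' @param latent_dim latent dimension `d`; must be even so the code splits
#'   into source and target halves (default 16).
#' @return a list of class `encoder_params` with `W0`, `W1_mu`, `W1_sigma`.
#' @export
init_encoder_params <- function(input_dim, hidden_dim = 32L,
                                latent_dim = 16L) {
  if (latent_dim %% 2L != 0L) stop("latent_dim must be even")
  structure(list(W0 = glorot(input_dim, hidden_dim),
                 W1_mu = glorot(hidden_dim, latent_dim),
                 W1_sigma = glorot(hidden_dim, latent_dim)),
            class = "encoder_params")
}

glorot <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

#' Initialize a two-layer dense expression decoder
#'
#' @param latent_dim input (latent) dimension.
#' @param hidden_dim hidden width.
#' @param output_dim number of output features per node.
#' @return a list of class `dense_decoder` with `V0`, `b0`, `V1`, `b1`.
#' @export
init_dense_decoder <- function(latent_dim, hidden_dim, output_dim) {
  structure(list(V0 = glorot(latent_dim, hidden_dim),
                 b0 = numeric(hidden_dim),
                 V1 = glorot(hidden_dim, output_dim),
                 b1 = numeric(output_dim)),
            class = "dense_decoder")
}

#' Two-layer directed GCN encoder
#'
#' Computes `mu = Ã H W1_mu` and `log_sigma = Ã H W1_sigma` with the shared
#' hidden representation `H = ReLU(Ã X W0)` computed once.
#'
#' @param A_norm row-normalized adjacency from [normalize_adjacency()].
#' @param features node feature matrix (rows align with adjacency nodes).
#' @param params an [init_encoder_params()] list.
#' @return a list of class `encoder_output` with `mu` and `log_sigma`
#'   (N x d each).
#' @export
encode <- function(A_norm, features, params) {
  features <- as.matrix(features)
  if (nrow(features) != nrow(A_norm))
    stop("feature rows must align with adjacency nodes")
  if (ncol(features) != nrow(params$W0))
    stop("feature dimension does not match W0")
  H <- pmax(A_norm %*% features %*% params$W0, 0)
  AH <- A_norm %*% H
  structure(list(mu = AH %*% params$W1_mu,
                 log_sigma = AH %*% params$W1_sigma),
            class = "encoder_output")
}

#' Sample latent codes from the variational posterior
#'
#' `Z = mu + exp(log_sigma) * eps` with standard normal `eps`; with
#' `eval = TRUE` the posterior mean is returned exactly (the deterministic
#' inference mode used for all downstream predictions).
#'
#' @param enc an `encoder_output`.
#' @param seed integer seed for the noise draw (ignored in eval mode).
#' @param eval logical; if `TRUE`, return `Z = mu` bit-exactly.
#' @return an N x d latent matrix.
#' @export
sample_latent <- function(enc, seed = 1L, eval = FALSE) {
  if (ncol(enc$mu) %% 2L != 0L) stop("latent dimension must be even")
  if (eval) return(enc$mu)
  set.seed(seed)
  eps <- matrix(rnorm(length(enc$mu)), nrow(enc$mu))
  enc$mu + exp(enc$log_sigma) * eps
}

#' Directed inner-product graph decoder
#'
#' `probs[i, j] = sigmoid(<z_i^(s), z_j^(t)>)` where the source half is the
#' first `d/2` latent dimensions and the target half the rest. The output
#' is generally asymmetric; the diagonal is computed like any other entry
#' (downstream analyses exclude it).
#'
#' @param Z N x d latent matrix, `d` even.
#' @return N x N matrix of edge probabilities in `[0, 1]`.
#' @export
decode_graph <- function(Z) {
  Z <- as.matrix(Z)
  d <- ncol(Z)
  if (d %% 2L != 0L) stop("latent dimension must be even")
  h <- d %/% 2L
  Zs <- Z[, seq_len(h), drop = FALSE]
  Zt <- Z[, h + seq_len(h), drop = FALSE]
  stats::plogis(Zs %*% t(Zt))
}

#' Two-layer dense expression decoder
#'
#' Maps each node's latent code through a ReLU hidden layer and a linear
#' output layer: for the gene-level autoencoder rows are genes and output
#' features are cells (rows of the reconstructed expression); for the
#' cell-level autoencoder rows are cells and output features are genes.
#'
#' @param Z N x d latent matrix.
#' @param decoder an [init_dense_decoder()] list.
#' @return N x output_dim reconstruction (node-major; transpose the
#'   cell-level output to reach the canonical genes x cells orientation).
#' @export
decode_expression <- function(Z, decoder) {
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(decoder$V0)) stop("latent dimension mismatch")
  Hd <- pmax(sweep(Z %*% decoder$V0, 2, decoder$b0, "+"), 0)
  sweep(Hd %*% decoder$V1, 2, decoder$b1, "+")
}

#' KL divergence of the variational posterior from the standard normal prior
#'
#' Per-node average of the closed form
#' `0.5 * sum(mu^2 + sigma^2 - 1 - 2 log sigma)` over nodes and latent
#' dimensions; always nonnegative. The per-node scaling balances the KL
#' against the per-entry-normalized reconstruction terms.
#'
#' @param enc an `encoder_output`.
#' @return a single nonnegative number.
#' @export
kl_divergence <- function(enc) {
  if (any(!is.finite(enc$mu)) || any(!is.finite(enc$log_sigma)))
    stop("non-finite encoder output")
  n <- nrow(enc$mu)
  s2 <- exp(2 * enc$log_sigma)
  0.5 * sum(enc$mu^2 + s2 - 1 - 2 * enc$log_sigma) / n
}
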