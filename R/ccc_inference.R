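# From a trained model to communication calls: the directed weighted
# cell-level network, cell-type aggregation with permutation p-values,
# ligand-receptor pair impact ranking, and spectral clustering of the
# inferred network.

#' Predict the directed cell-cell communication network
#'
#' Deterministic inference: the cell-level encoder is evaluated at the
#' posterior mean (`Z = mu`, no sampling) and the directed inner-product
#' decoder produces the edge-probability matrix; entries are the predicted
#' communication strengths. Binary edges are the ordered off-diagonal pairs
#' with probability at or above the cutoff.
#'
#' @param model a [train()]ed model.
#' @param expr the [expression_matrix] to run inference on (same genes and
#'   cells as training).
#' @param A_c the spatial graph used for message passing during encoding.
#' @param cutoff binarization cutoff on probabilities (default 0.5).
#' @return a list of class `ccc_network` with `probs` (n x n, dimnames =
#'   cell IDs), `edges` (logical n x n, diagonal always `FALSE`) and
#'   `cutoff`.
#' @export
predict_ccc_network <- function(model, expr, A_c, cutoff = 0.5) {
  X <- unclass(expr)
  if (nrow(X) != model$dims$m || ncol(X) != model$dims$n)
    stop("dimension mismatch with checkpoint")
  Ac <- adjacency_of(A_c)
  if (nrow(Ac) != ncol(X)) stop("cell graph size does not match expression")
  An <- normalize_adjacency(Ac)
  enc <- encode(An, t(X), model$cell$enc)
  probs <- decode_graph(enc$mu)
  dimnames(probs) <- list(colnames(X), colnames(X))
  edges <- probs >= cutoff
  diag(edges) <- FALSE
  structure(list(probs = probs, edges = edges, cutoff = cutoff),
            class = "ccc_network")
}

#' @export
print.ccc_network <- function(x, ...) {
  cat(sprintf("ccc_network: %d cells, %d directed edges at cutoff %g\n",
              nrow(x$probs), sum(x$edges), x$cutoff))
  invisible(x)
}

#' Export the binary communication edges as a weighted edge list
#'
#' @param net a [predict_ccc_network()] result.
#' @return data.frame with `source`, `target`, `weight` (the probability).
#' @export
network_edge_list <- function(net) {
  idx <- which(net$edges, arr.ind = TRUE)
  ids <- rownames(net$probs)
  df <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                   weight = net$probs[idx], stringsAsFactors = FALSE)
  df[order(df$source, df$target), , drop = FALSE]
}

type_strengths <- function(probs, type_idx, K) {
  n <- length(type_idx)
  Ind <- matrix(0, n, K)
  Ind[cbind(seq_len(n), type_idx)] <- 1
  num <- crossprod(Ind, probs %*% Ind)
  diag_by_type <- vapply(seq_len(K), function(k)
    sum(diag(probs)[type_idx == k]), numeric(1))
  diag(num) <- diag(num) - diag_by_type
  nk <- colSums(Ind)
  cnt <- outer(nk, nk)
  diag(cnt) <- diag(cnt) - nk
  s <- num / ifelse(cnt == 0, 1, cnt)
  s[cnt == 0] <- 0  # single-cell types: within-type mean over zero pairs
  s
}

#' Aggregate the communication network to cell-type level
#'
#' The strength from type k to type l is the average predicted communication
#' weight over all ordered cell pairs (sender of type k, receiver of type
#' l), self-pairs excluded. A type with a single cell has no valid
#' within-type pair; its within-type strength is 0 by convention.
#'
#' @param net a [predict_ccc_network()] result.
#' @param labels a [cell_labels] vector covering all cells in the network.
#' @return a list of class `celltype_comm` with `strength` (K x K,
#'   sender types in rows) and `types`.
#' @export
aggregate_by_cell_type <- function(net, labels) {
  ids <- rownames(net$probs)
  if (!all(ids %in% names(labels))) stop("unknown label: cells missing")
  lab <- as.character(unclass(labels)[ids])
  types <- sort(unique(lab))
  ti <- match(lab, types)
  s <- type_strengths(net$probs, ti, length(types))
  dimnames(s) <- list(types, types)
  structure(list(strength = s, types = types), class = "celltype_comm")
}

#' Permutation test of cell-type communication strengths
#'
#' Cell-type labels are permuted uniformly at random as a whole vector
#' `n_perm` times; for each ordered type pair the p-value is the
#' permutation percentile of the observed strength,
#' `p = (1 + #{permuted >= observed}) / (1 + n_perm)`, so p-values lie in
#' `(0, 1]` and are never exactly zero.
#'
#' @param net a [predict_ccc_network()] result.
#' @param labels a [cell_labels] vector.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; results are deterministic given it.
#' @return a `celltype_comm` list with `strength`, `pvalue` (both K x K)
#'   and `n_perm`.
#' @export
permutation_test <- function(net, labels, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  ids <- rownames(net$probs)
  if (!all(ids %in% names(labels))) stop("unknown label: cells missing")
  lab <- as.character(unclass(labels)[ids])
  types <- sort(unique(lab))
  K <- length(types)
  ti <- match(lab, types)
  obs <- type_strengths(net$probs, ti, K)
  set.seed(seed)
  exceed <- matrix(0L, K, K)
  for (b in seq_len(n_perm)) {
    sp <- type_strengths(net$probs, sample(ti), K)
    exceed <- exceed + (sp >= obs)
  }
  pv <- (1 + exceed) / (1 + n_perm)
  dimnames(obs) <- dimnames(pv) <- list(types, types)
  structure(list(strength = obs, pvalue = pv, n_perm = as.integer(n_perm),
                 types = types),
            class = "celltype_comm")
}

#' @export
print.celltype_comm <- function(x, ...) {
  cat(sprintf("celltype_comm: %d types (sender in rows)\n", length(x$types)))
  cat("strength:\n")
  print(round(x$strength, 4))
  if (!is.null(x$pvalue)) {
    cat(sprintf("permutation p-values (n_perm=%d):\n", x$n_perm))
    print(round(x$pvalue, 4))
  }
  invisible(x)
}

count_type_edges <- function(net, labels, sender, receiver) {
  ids <- rownames(net$probs)
  lab <- as.character(unclass(labels)[ids])
  si <- which(lab == sender); ri <- which(lab == receiver)
  if (!length(si) || !length(ri)) stop("unknown cell type")
  sub <- net$edges[si, ri, drop = FALSE]
  sum(sub)
}

#' Edge-reduction ratio of one ligand-receptor gene edge
#'
#' Retrains the model on the gene graph with the given ligand->receptor
#' edge removed (same seed and hyperparameters as the reference run, so the
#' ratio isolates the edge's effect) and reports the proportion of predicted
#' sender-type -> receiver-type communications lost relative to the
#' complete-network run:
#' `ratio = max(0, (E_full - E_perturbed) / E_full)`, 0 when `E_full` is 0.
#'
#' @param expr an [expression_matrix].
#' @param A_c spatial graph.
#' @param A_g gene graph containing the edge.
#' @param lr_edge length-2 character vector `c(ligand_gene, receptor_gene)`.
#' @param sender,receiver cell-type names whose directed communication is
#'   counted.
#' @param labels a [cell_labels] vector.
#' @param hyperparams training hyperparameters.
#' @param seed training seed (shared by reference and perturbed runs).
#' @param cutoff binarization cutoff for edge counts.
#' @param reference optional precomputed reference `ccc_network` from the
#'   unperturbed graph (saves one retrain in batch use).
#' @return the edge-reduction ratio in `[0, 1]`.
#' @export
lr_pair_impact <- function(expr, A_c, A_g, lr_edge, sender, receiver,
                           labels, hyperparams = default_hyperparams(),
                           seed = 1L, cutoff = 0.5, reference = NULL) {
  Ag <- adjacency_of(A_g)
  if (length(lr_edge) != 2L || !all(lr_edge %in% rownames(Ag)) ||
      Ag[lr_edge[1], lr_edge[2]] != 1)
    stop("lr_edge is not present in the gene graph")
  if (is.null(reference)) {
    ref_model <- train(expr, A_c, Ag, hyperparams, seed)
    reference <- predict_ccc_network(ref_model, expr, A_c, cutoff)
  }
  E_full <- count_type_edges(reference, labels, sender, receiver)
  if (E_full == 0) return(0)
  Ag2 <- Ag
  Ag2[lr_edge[1], lr_edge[2]] <- 0
  pert_model <- train(expr, A_c, Ag2, hyperparams, seed)
  pert_net <- predict_ccc_network(pert_model, expr, A_c, cutoff)
  E_pert <- count_type_edges(pert_net, labels, sender, receiver)
  max(0, (E_full - E_pert) / E_full)
}

#' Impact table for a set of ligand-receptor edges
#'
#' Batch driver around [lr_pair_impact()]: trains the reference once, then
#' one perturbed retrain per requested gene-graph edge.
#'
#' @param expr,A_c,A_g,labels,hyperparams,seed,cutoff as in
#'   [lr_pair_impact()].
#' @param sender,receiver the cell-type pair whose communications are
#'   counted.
#' @param pairs data.frame with `ligand`, `receptor` columns; defaults to
#'   every edge of the gene graph.
#' @return data.frame of class `lr_impact_table` with columns `ligand`,
#'   `receptor`, `sender`, `receiver`, `edge_reduction_ratio`.
#' @export
lr_impact_table <- function(expr, A_c, A_g, sender, receiver, labels,
                            pairs = NULL,
                            hyperparams = default_hyperparams(),
                            seed = 1L, cutoff = 0.5) {
  Ag <- adjacency_of(A_g)
  if (is.null(pairs)) {
    idx <- which(Ag == 1, arr.ind = TRUE)
    pairs <- data.frame(ligand = rownames(Ag)[idx[, 1]],
                        receptor = colnames(Ag)[idx[, 2]],
                        stringsAsFactors = FALSE)
  }
  ref_model <- train(expr, A_c, Ag, hyperparams, seed)
  reference <- predict_ccc_network(ref_model, expr, A_c, cutoff)
  ratios <- vapply(seq_len(nrow(pairs)), function(i) {
    lr_pair_impact(expr, A_c, Ag,
                   c(pairs$ligand[i], pairs$receptor[i]),
                   sender, receiver, labels, hyperparams, seed, cutoff,
                   reference = reference)
  }, numeric(1))
  out <- data.frame(ligand = pairs$ligand, receptor = pairs$receptor,
                    sender = sender, receiver = receiver,
                    edge_reduction_ratio = ratios,
                    stringsAsFactors = FALSE)
  class(out) <- c("lr_impact_table", class(out))
  out
}

#' Rank ligand-receptor pairs by impact
#'
#' Sorts an impact table by edge-reduction ratio descending (ties broken by
#' ligand then receptor gene name), assigns dense ranks (equal ratios share
#' a rank) and returns the top `top_k` rows.
#'
#' @param impacts an [lr_impact_table()] for one (sender, receiver) pair.
#' @param top_k number of key pairs to keep (default 20, the usual
#'   reporting choice); larger than the table returns everything.
#' @return the ranked table with a `rank` column.
#' @export
rank_lr_pairs <- function(impacts, top_k = 20L) {
  ord <- order(-impacts$edge_reduction_ratio, impacts$ligand,
               impacts$receptor)
  out <- impacts[ord, , drop = FALSE]
  ratios <- out$edge_reduction_ratio
  out$rank <- match(ratios, sort(unique(ratios), decreasing = TRUE))
  out <- utils::head(out, min(top_k, nrow(out)))
  rownames(out) <- NULL
  out
}

#' Spectral clustering of the inferred communication network
#'
#' Standard normalized spectral clustering on the symmetrized affinity
#' `(probs + t(probs)) / 2` (diagonal zeroed): leading eigenvectors of the
#' symmetrically normalized affinity, row-normalized, then k-means.
#' Cluster IDs are arbitrary; compare partitions, not labels. `k = n`
#' trivially assigns each cell its own cluster.
#'
#' @param net a [predict_ccc_network()] result.
#' @param k number of clusters (2 <= k <= n).
#' @param seed seed for the k-means initialization.
#' @return integer vector of cluster labels named by cell ID.
#' @export
spectral_clusters <- function(net, k, seed = 1L) {
  W <- (net$probs + t(net$probs)) / 2
  diag(W) <- 0
  n <- nrow(W)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed the number of cells")
  if (k == n) return(setNames(seq_len(n), rownames(W)))
  dg <- rowSums(W)
  dg[dg == 0] <- 1
  Dm <- 1 / sqrt(dg)
  Wn <- W * outer(Dm, Dm)
  ev <- eigen(Wn, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn == 0, 1, rn)
  set.seed(seed)
  cl <- stats::kmeans(U, centers = k, nstart = 10L, iter.max = 50L)
  setNames(cl$cluster, rownames(W))
}
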