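# Synthetic spatial-transcriptomics data with known ground-truth
# communication: cells are placed as per-type Gaussian blobs, a minority of
# ordered type pairs is designated communicating, and for every ground-truth
# sender/receiver pair within the neighbor radius the pair's ligand gene
# (sender) and receptor gene (receiver) are amplified on top of lognormal
# multiplicative background noise.

#' Parameters for the synthetic dataset generator
#'
#' @param n_cells number of cells/spots.
#' @param n_genes number of genes; must be at least `2 * n_lr_pairs` so that
#'   each ligand-receptor pair has its own two genes.
#' @param n_types number of cell types (spatial Gaussian blobs).
#' @param n_lr_pairs number of ligand-receptor gene pairs in the database.
#' @param domain_size side length of the square spatial domain (same units
#'   as `neighbor_radius`; think micrometres).
#' @param neighbor_radius maximum sender-receiver distance of a ground-truth
#'   communication edge.
#' @param signal_strength multiplicative over-expression of the ligand gene
#'   in senders and the receptor gene in receivers: the affected entry is
#'   scaled by `1 + signal_strength`, so 0 means no signal.
#' @param noise_dispersion sdlog of the lognormal multiplicative background
#'   noise.
#' @param comm_fraction fraction of ordered type pairs designated as
#'   communicating (at least one pair is always designated).
#' @param blob_sd standard deviation of each type's spatial blob; defaults
#'   to `domain_size / 8`.
#' @param seed integer seed; the generator is a pure function of the
#'   parameters including the seed.
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(n_cells = 200L, n_genes = 60L, n_types = 4L,
                         n_lr_pairs = 10L, domain_size = 1000,
                         neighbor_radius = 150, signal_strength = 5,
                         noise_dispersion = 0.3, comm_fraction = 0.25,
                         blob_sd = domain_size / 8, seed = 1L) {
  p <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
            n_types = as.integer(n_types), n_lr_pairs = as.integer(n_lr_pairs),
            domain_size = domain_size, neighbor_radius = neighbor_radius,
            signal_strength = signal_strength,
            noise_dispersion = noise_dispersion,
            comm_fraction = comm_fraction, blob_sd = blob_sd,
            seed = as.integer(seed))
  if (p$n_genes < 2L * p$n_lr_pairs)
    stop("n_genes must be at least 2 * n_lr_pairs")
  if (p$n_cells < p$n_types) stop("n_cells must be at least n_types")
  if (!(p$neighbor_radius < p$domain_size))
    stop("neighbor_radius must be smaller than domain_size")
  if (p$signal_strength < 0 || p$noise_dispersion < 0)
    stop("signal_strength and noise_dispersion must be nonnegative")
  class(p) <- "synth_params"
  p
}

#' Generate a synthetic spatial dataset with known communication structure
#'
#' Cells are placed as per-type Gaussian blobs inside the square domain; a
#' fixed minority of ordered type pairs is designated communicating, each
#' carried by one ligand-receptor gene pair. Every ordered cell pair whose
#' types match a communicating design entry and whose distance is at most
#' `neighbor_radius` becomes a ground-truth edge: the sender over-expresses
#' the pair's ligand gene and the receiver its receptor gene by the factor
#' `1 + signal_strength` on top of lognormal multiplicative noise.
#'
#' @param params a [synth_params] object.
#' @return a list of class `synthetic_dataset` with elements `expression`
#'   ([expression_matrix]), `coords` ([spatial_coords]), `labels`
#'   ([cell_labels]), `lr_db` ([lr_database]), `truth_edges` (data.frame
#'   sender/receiver/lr_pair/distance), `truth_type_matrix` (K x K binary,
#'   sender type in rows), `signal_genes` (character) and `params`.
#' @export
generate_dataset <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  cell_ids <- sprintf("c%03d", seq_len(p$n_cells))
  gene_ids <- sprintf("G%03d", seq_len(p$n_genes))
  type_names <- sprintf("T%d", seq_len(p$n_types))

  # spatial blobs: one centre per type, cells assigned round-robin so every
  # type is populated even at small n_cells
  centres <- cbind(runif(p$n_types, 0.2, 0.8) * p$domain_size,
                   runif(p$n_types, 0.2, 0.8) * p$domain_size)
  type_idx <- rep_len(seq_len(p$n_types), p$n_cells)
  xy <- centres[type_idx, , drop = FALSE] +
    matrix(rnorm(2L * p$n_cells, 0, p$blob_sd), ncol = 2)
  xy <- pmin(pmax(xy, 0), p$domain_size)
  coords <- spatial_coords(xy, cell_ids = cell_ids)
  labels <- cell_labels(type_names[type_idx], cell_ids = cell_ids)

  # LR database: pair k uses genes 2k-1 (ligand) and 2k (receptor)
  lig_genes <- gene_ids[2L * seq_len(p$n_lr_pairs) - 1L]
  rec_genes <- gene_ids[2L * seq_len(p$n_lr_pairs)]
  lr_db <- lr_database(as.list(lig_genes), as.list(rec_genes),
                       annotation = sprintf("synthetic pair %d",
                                            seq_len(p$n_lr_pairs)))

  # communicating type design: a fixed minority of ordered type pairs,
  # each assigned one LR pair (cycled if there are more design entries
  # than pairs)
  all_pairs <- expand.grid(sender = seq_len(p$n_types),
                           receiver = seq_len(p$n_types))
  n_comm <- max(1L, round(p$comm_fraction * nrow(all_pairs)))
  comm_sel <- sort(sample.int(nrow(all_pairs), n_comm))
  truth_type_matrix <- matrix(0L, p$n_types, p$n_types,
                              dimnames = list(type_names, type_names))
  pair_of_design <- matrix(NA_integer_, p$n_types, p$n_types)
  for (d in seq_along(comm_sel)) {
    s <- all_pairs$sender[comm_sel[d]]
    r <- all_pairs$receiver[comm_sel[d]]
    truth_type_matrix[s, r] <- 1L
    pair_of_design[s, r] <- ((d - 1L) %% p$n_lr_pairs) + 1L
  }

  # background: per-gene base mean times lognormal multiplicative noise
  base_mean <- runif(p$n_genes, 0.5, 2)
  noise <- matrix(rlnorm(p$n_genes * p$n_cells, meanlog = 0,
                         sdlog = p$noise_dispersion),
                  p$n_genes, p$n_cells)
  expr_vals <- base_mean * noise

  # ground-truth edges: ordered pairs within radius whose types communicate
  dmat <- as.matrix(stats::dist(xy))
  within <- dmat <= p$neighbor_radius
  diag(within) <- FALSE
  comm <- truth_type_matrix[type_idx, type_idx] == 1L
  edge_idx <- which(within & comm, arr.ind = TRUE)
  lr_of_edge <- pair_of_design[cbind(type_idx[edge_idx[, 1]],
                                     type_idx[edge_idx[, 2]])]
  truth_edges <- data.frame(
    sender = cell_ids[edge_idx[, 1]],
    receiver = cell_ids[edge_idx[, 2]],
    lr_pair = lr_of_edge,
    distance = dmat[edge_idx],
    stringsAsFactors = FALSE
  )
  truth_edges <- truth_edges[order(edge_idx[, 1], edge_idx[, 2]), ,
                             drop = FALSE]
  rownames(truth_edges) <- NULL

  # amplify once per (gene, cell), however many edges the cell takes part in
  boost <- matrix(FALSE, p$n_genes, p$n_cells)
  if (nrow(truth_edges)) {
    li <- match(lig_genes[truth_edges$lr_pair], gene_ids)
    ri <- match(rec_genes[truth_edges$lr_pair], gene_ids)
    si <- match(truth_edges$sender, cell_ids)
    ti <- match(truth_edges$receiver, cell_ids)
    boost[cbind(li, si)] <- TRUE
    boost[cbind(ri, ti)] <- TRUE
  }
  expr_vals[boost] <- expr_vals[boost] * (1 + p$signal_strength)

  out <- list(
    expression = expression_matrix(expr_vals, gene_ids, cell_ids),
    coords = coords,
    labels = labels,
    lr_db = lr_db,
    truth_edges = truth_edges,
    truth_type_matrix = truth_type_matrix,
    signal_genes = as.character(rbind(lig_genes, rec_genes)[
      , sort(unique(truth_edges$lr_pair)), drop = FALSE]),
    params = p
  )
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_dataset: %d genes x %d cells, %d types, %d LR pairs, ",
    "%d truth edges\n"),
    nrow(x$expression), ncol(x$expression), x$params$n_types,
    x$params$n_lr_pairs, nrow(x$truth_edges)))
  invisible(x)
}

#' Random dropout corruption of an expression matrix
#'
#' Each entry is independently set to zero with probability `dropout_rate`;
#' deterministic given the seed.
#'
#' @param expr an [expression_matrix].
#' @param dropout_rate fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return an [expression_matrix] of the same shape.
#' @export
corrupt_expression <- function(expr, dropout_rate, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  vals <- unclass(expr)
  if (dropout_rate > 0) {
    set.seed(seed)
    drop <- matrix(runif(length(vals)) < dropout_rate, nrow(vals))
    vals[drop] <- 0
  }
  expression_matrix(vals, rownames(expr), colnames(expr))
}
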