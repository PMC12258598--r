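# Spatial cell/spot graph and directed ligand-receptor gene graph.
#
# The spatial graph connects two cells iff their Euclidean distance is
# strictly below the threshold (ties at exactly the threshold are excluded).
# The gene graph is the database expansion of ligand->receptor subunit pairs
# restricted to genes present and passing the expression gate.

#' Build the spatial neighbor graph
#'
#' Binary symmetric adjacency with `A[i, j] = 1` iff the Euclidean distance
#' between cells i and j is strictly smaller than `threshold`; the diagonal
#' is zero. Coordinates are treated as planar Euclidean; units are the
#' caller's responsibility (radius thresholds in the literature are
#' platform-specific, e.g. 300 um for STARmap-scale single-cell data).
#'
#' @param coords a [spatial_coords] matrix (>= 2 cells).
#' @param threshold positive distance threshold.
#' @return a list of class `spatial_graph` with `adjacency` (binary
#'   symmetric matrix, dimnames = cell IDs) and `threshold_used`.
#' @export
build_spatial_graph <- function(coords, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  xy <- unclass(coords)
  if (nrow(xy) < 2L) stop("at least two cells are required")
  if (any(!is.finite(xy))) stop("non-finite coordinates")
  d <- as.matrix(stats::dist(xy))
  adj <- (d < threshold) * 1
  diag(adj) <- 0
  dimnames(adj) <- list(rownames(xy), rownames(xy))
  structure(list(adjacency = adj, threshold_used = threshold),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph: %d cells, %d undirected edges, threshold %g\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$threshold_used))
  invisible(x)
}

#' Select a distance threshold by the minimum-neighbor heuristic
#'
#' Returns the smallest candidate threshold under which strictly more than
#' `fraction` of cells have at least `min_neighbors` spatial neighbors —
#' the standard heuristic that most cells in a two-dimensional tissue touch
#' at least three neighboring cells. If no candidate qualifies, the largest
#' candidate is returned with a warning.
#'
#' @param coords a [spatial_coords] matrix.
#' @param min_neighbors minimum neighbor count per cell (default 3).
#' @param fraction required fraction of cells meeting the minimum
#'   (default 0.8, i.e. over 80 percent).
#' @param candidates increasing positive candidate thresholds; defaults to
#'   20 log-spaced values between the 1st and 50th percentile of nonzero
#'   pairwise distances.
#' @return the selected threshold (a single positive number).
#' @export
select_distance_threshold <- function(coords, min_neighbors = 3L,
                                      fraction = 0.8, candidates = NULL) {
  xy <- unclass(coords)
  d <- as.matrix(stats::dist(xy))
  if (is.null(candidates)) {
    nz <- d[upper.tri(d)]
    nz <- nz[nz > 0]
    if (!length(nz)) stop("all cells are co-located; supply candidates")
    qs <- stats::quantile(nz, c(0.01, 0.5), names = FALSE)
    if (qs[1] <= 0) qs[1] <- min(nz)
    candidates <- exp(seq(log(qs[1]), log(qs[2]), length.out = 20L))
  }
  if (!length(candidates)) stop("empty candidate list")
  if (is.unsorted(candidates)) stop("candidates must be sorted ascending")
  n <- nrow(xy)
  for (t in candidates) {
    deg <- rowSums(d < t) - 1L  # subtract self (distance 0)
    if (mean(deg >= min_neighbors) > fraction) return(t)
  }
  warning(sprintf(
    "no candidate gives >%g%% of cells >=%d neighbors; using largest (%g)",
    100 * fraction, min_neighbors, max(candidates)))
  max(candidates)
}

#' Build the directed ligand-receptor gene graph
#'
#' Each database record is expanded to all ordered (ligand subunit ->
#' receptor subunit) gene pairs. A directed edge is added iff both genes
#' are present in the expression matrix and each is nonzero in at least
#' `min_cells_expressing` cells (the expression gate: both genes of an
#' interaction must be expressed in the dataset). Records whose genes are
#' absent are skipped and counted, never fatal.
#'
#' @param lr_db an [lr_database].
#' @param expr an [expression_matrix]; gene symbols are matched exactly
#'   (case-sensitive, after trimming).
#' @param min_cells_expressing expression gate (default 1); 0 disables the
#'   gate, leaving pure database expansion over present genes.
#' @return a list of class `gene_graph` with `adjacency` (binary directed
#'   m x m matrix, ligand row -> receptor column, dimnames = gene IDs),
#'   `pair_index` (data.frame ligand/receptor/record mapping edges back to
#'   database records) and `n_skipped_records`.
#' @export
build_gene_graph <- function(lr_db, expr, min_cells_expressing = 1L) {
  genes <- rownames(expr)
  m <- length(genes)
  expressed <- rowSums(unclass(expr) > 0) >= min_cells_expressing
  names(expressed) <- genes
  adj <- matrix(0, m, m, dimnames = list(genes, genes))
  pi_lig <- character(0); pi_rec <- character(0); pi_rec_id <- integer(0)
  skipped <- 0L
  for (r in seq_len(nrow(lr_db))) {
    ls <- lr_db$ligand_subunits[[r]]
    rs <- lr_db$receptor_subunits[[r]]
    if (!all(c(ls, rs) %in% genes)) {
      skipped <- skipped + 1L
      next
    }
    for (l in ls) for (g in rs) {
      if (l == g) next  # no self-loops in the gene graph
      if (expressed[l] && expressed[g]) {
        adj[l, g] <- 1
        pi_lig <- c(pi_lig, l); pi_rec <- c(pi_rec, g)
        pi_rec_id <- c(pi_rec_id, r)
      }
    }
  }
  structure(list(
    adjacency = adj,
    pair_index = data.frame(ligand = pi_lig, receptor = pi_rec,
                            record = pi_rec_id, stringsAsFactors = FALSE),
    n_skipped_records = skipped
  ), class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d genes, %d directed LR edges (%d records skipped)\n",
              nrow(x$adjacency), sum(x$adjacency), x$n_skipped_records))
  invisible(x)
}

#' Histogram of communicating cell pairs by distance
#'
#' Assigns each directed edge to the half-open distance bin
#' `[b_k, b_{k+1})` containing its Euclidean length; out-of-range edges are
#' dropped, so counts sum to the number of in-range edges.
#'
#' @param edges data.frame with `source` and `target` columns of cell IDs
#'   (extra columns ignored).
#' @param coords a [spatial_coords] matrix covering all edge endpoints.
#' @param bin_edges increasing numeric bin boundaries.
#' @return integer vector of counts, one per bin, named by the bin
#'   intervals.
#' @export
count_edges_by_distance <- function(edges, coords, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  nb <- length(bin_edges) - 1L
  labs <- sprintf("[%g,%g)", bin_edges[-length(bin_edges)], bin_edges[-1])
  counts <- setNames(integer(nb), labs)
  if (!nrow(edges)) return(counts)
  xy <- unclass(coords)
  s <- xy[as.character(edges$source), , drop = FALSE]
  t <- xy[as.character(edges$target), , drop = FALSE]
  len <- sqrt(rowSums((s - t)^2))
  bin <- findInterval(len, bin_edges, rightmost.closed = FALSE)
  keep <- bin >= 1L & bin <= nb & len < bin_edges[length(bin_edges)]
  tab <- tabulate(bin[keep], nbins = nb)
  counts[] <- tab
  counts
}
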