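# Evaluation machinery: average precision and AUC for edge recovery,
# per-gene sensitivity analysis, and the edge-removal / fake-edge
# robustness protocol with repeated runs.

#' Average precision (area under the precision-recall curve)
#'
#' Candidates are ranked by score descending (ties broken by the fixed
#' candidate ordering, i.e. a stable sort) and AP is the mean of the
#' precision at each positive's rank — the standard rank-based area under
#' the precision-recall curve.
#'
#' @param scores numeric score per candidate edge.
#' @param reference binary (0/1 or logical) relevance per candidate.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, reference) {
  reference <- as.numeric(reference)
  if (length(scores) != length(reference)) stop("length mismatch")
  npos <- sum(reference == 1)
  if (npos == 0) stop("average precision needs at least one positive")
  ord <- order(-scores)  # stable: ties keep candidate order
  rel <- reference[ord]
  prec_at <- cumsum(rel) / seq_along(rel)
  sum(prec_at[rel == 1]) / npos
}

#' AUC in exact Mann-Whitney form
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)` computed exactly from midranks
#' over all positive-negative pairs.
#'
#' @param scores_pos scores of the positive samples (existing edges).
#' @param scores_neg scores of the negative samples (non-edges).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0 || nn == 0) stop("both score sets must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

offdiag_index <- function(n) {
  which(row(diag(n)) != col(diag(n)))  # fixed column-major candidate order
}

ap_against_graph <- function(probs, Ac) {
  idx <- offdiag_index(nrow(probs))
  average_precision(probs[idx], Ac[idx])
}

#' Edge-recovery AUC of a predicted network against a spatial graph
#'
#' Positives are the ordered off-diagonal edges of `A_c`; negatives an
#' equal-sized uniform sample of ordered non-edges; scores are the
#' predicted probabilities.
#'
#' @param net a [predict_ccc_network()] result.
#' @param A_c the spatial graph (or bare adjacency).
#' @param seed seed for the negative sample.
#' @return AUC in `[0, 1]`.
#' @export
reconstruction_auc <- function(net, A_c, seed = 1L) {
  Ac <- adjacency_of(A_c)
  idx <- offdiag_index(nrow(Ac))
  pos <- idx[Ac[idx] == 1]
  neg_pool <- idx[Ac[idx] == 0]
  if (!length(pos)) stop("the graph has no edges")
  set.seed(seed)
  neg <- sample(neg_pool, min(length(pos), length(neg_pool)))
  auc(net$probs[pos], net$probs[neg])
}

perturb_gene <- function(X, gene, mode, seed) {
  Xp <- X
  if (mode == "zero-mask") {
    Xp[gene, ] <- 0
  } else {
    set.seed(seed)
    Xp[gene, ] <- Xp[gene, sample(ncol(Xp))]
  }
  Xp
}

#' Sensitivity score of one gene
#'
#' Perturbs the gene's expression across all cells (zero-masking by
#' default, or a within-gene shuffle), reruns deterministic inference with
#' the trained model, and reports the absolute change in average precision
#' of recovering the spatial graph's edges:
#' `score = |AP_perturbed - AP_baseline|`. Inference-only by design, so the
#' score is fully deterministic; genes whose perturbation leaves the matrix
#' unchanged score exactly 0.
#'
#' @param model a [train()]ed model.
#' @param expr the [expression_matrix] used at baseline.
#' @param A_c the spatial graph (positives for AP).
#' @param gene gene ID to perturb.
#' @param mode `"zero-mask"` (default) or `"shuffle"`.
#' @param seed seed for the shuffle mode.
#' @param baseline_ap optional precomputed baseline AP (saves recomputation
#'   in batch use).
#' @return a single nonnegative number.
#' @export
gene_sensitivity <- function(model, expr, A_c, gene,
                             mode = c("zero-mask", "shuffle"), seed = 1L,
                             baseline_ap = NULL) {
  mode <- match.arg(mode)
  X <- unclass(expr)
  if (!gene %in% rownames(X)) stop("unknown gene: ", gene)
  Ac <- adjacency_of(A_c)
  if (is.null(baseline_ap)) {
    base_net <- predict_ccc_network(model, expr, Ac)
    baseline_ap <- ap_against_graph(base_net$probs, Ac)
  }
  Xp <- perturb_gene(X, gene, mode, seed)
  pert_net <- predict_ccc_network(
    model, expression_matrix(Xp, rownames(X), colnames(X)), Ac)
  abs(ap_against_graph(pert_net$probs, Ac) - baseline_ap)
}

#' Sensitivity scores for all (or a subset of) genes
#'
#' @param model,expr,A_c,mode,seed as in [gene_sensitivity()].
#' @param genes genes to score (default: all).
#' @return a named nonnegative numeric vector with attribute
#'   `baseline_ap`.
#' @export
gene_sensitivity_all <- function(model, expr, A_c, genes = rownames(expr),
                                 mode = c("zero-mask", "shuffle"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  Ac <- adjacency_of(A_c)
  base_net <- predict_ccc_network(model, expr, Ac)
  base_ap <- ap_against_graph(base_net$probs, Ac)
  scores <- vapply(genes, function(g)
    gene_sensitivity(model, expr, Ac, g, mode, seed, baseline_ap = base_ap),
    numeric(1))
  attr(scores, "baseline_ap") <- base_ap
  scores
}

#' Rank the most sensitive genes
#'
#' Sorts genes by sensitivity score descending (ties broken by gene name)
#' and returns the top `ceil(top_fraction * m)` — e.g. the top 8 or 10
#' percent typically taken forward to enrichment analysis.
#'
#' @param scores named numeric vector from [gene_sensitivity_all()].
#' @param top_fraction fraction in `(0, 1]`.
#' @return character vector of gene IDs, most sensitive first.
#' @export
rank_sensitive_genes <- function(scores, top_fraction) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  ord <- order(-scores, names(scores))
  utils::head(names(scores)[ord], ceiling(top_fraction * length(scores)))
}

# shared AUC scoring of a perturbed run against a reference
score_perturbed <- function(pert_probs, positives, neg_pool, seed) {
  set.seed(seed)
  neg <- sample(neg_pool, min(length(positives), length(neg_pool)))
  auc(pert_probs[positives], pert_probs[neg])
}

undirected_edge_index <- function(Ac) {
  which(Ac == 1 & upper.tri(Ac))
}

sym_drop <- function(Ac, lin_idx) {
  n <- nrow(Ac)
  r <- (lin_idx - 1L) %% n + 1L
  c <- (lin_idx - 1L) %/% n + 1L
  Ac[cbind(r, c)] <- 0
  Ac[cbind(c, r)] <- 0
  Ac
}

sym_add <- function(Ac, lin_idx) {
  n <- nrow(Ac)
  r <- (lin_idx - 1L) %% n + 1L
  c <- (lin_idx - 1L) %/% n + 1L
  Ac[cbind(r, c)] <- 1
  Ac[cbind(c, r)] <- 1
  Ac
}

robustness_run <- function(expr, A_c, A_g, levels, n_reps, hyperparams,
                           base_seed, scenario, compare, cutoff) {
  Ac <- adjacency_of(A_c)
  Ag <- adjacency_of(A_g)
  n <- nrow(Ac)
  und <- undirected_edge_index(Ac)
  E <- length(und)
  nonedge_und <- which(Ac == 0 & upper.tri(Ac))
  set.seed(base_seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(levels) * n_reps),
                      length(levels), n_reps)
  ref_model <- train(expr, Ac, Ag, hyperparams, base_seed)
  ref_net <- predict_ccc_network(ref_model, expr, Ac, cutoff)
  offd <- offdiag_index(n)
  ref_pos <- offd[ref_net$edges[offd]]
  ref_neg_pool <- offd[!ref_net$edges[offd]]
  aucs <- matrix(NA_real_, length(levels), n_reps,
                 dimnames = list(as.character(levels), NULL))
  for (li in seq_along(levels)) {
    lev <- levels[li]
    for (rp in seq_len(n_reps)) {
      rs <- rep_seeds[li, rp]
      set.seed(rs)
      if (scenario == "remove") {
        n_del <- round(lev * E)
        if (E - n_del <= 0) stop("deletion ratio leaves zero edges")
        del <- if (n_del > 0) sample(und, n_del) else integer(0)
        Ac2 <- sym_drop(Ac, del)
      } else {
        n_add <- round(lev * E)
        if (n_add > length(nonedge_und))
          stop("not enough non-edges to add the requested fake edges")
        add <- if (n_add > 0) sample(nonedge_und, n_add) else integer(0)
        Ac2 <- sym_add(Ac, add)
      }
      pert_model <- train(expr, Ac2, Ag, hyperparams, base_seed)
      pert_net <- predict_ccc_network(pert_model, expr, Ac2, cutoff)
      if (compare == "predictions") {
        aucs[li, rp] <- score_perturbed(pert_net$probs, ref_pos,
                                        ref_neg_pool, rs + 1L)
      } else {  # heldout: recover the deleted edges themselves
        both_dir <- function(lin) {
          r <- (lin - 1L) %% n + 1L; c <- (lin - 1L) %/% n + 1L
          c((c - 1L) * n + r, (r - 1L) * n + c)
        }
        pos <- both_dir(del)
        neg_pool <- offd[Ac[offd] == 0]
        aucs[li, rp] <- score_perturbed(pert_net$probs, pos, neg_pool,
                                        rs + 1L)
      }
    }
  }
  structure(list(scenario = scenario, levels = levels, auc = aucs,
                 n_replicates = as.integer(n_reps), seeds = rep_seeds,
                 compare = compare, base_seed = base_seed),
            class = "robustness_result")
}

#' Robustness to missing spatial edges
#'
#' For each deletion ratio and replicate, a uniform sample of undirected
#' spatial edges is removed (symmetrically), the model is retrained from
#' the same seed, and an AUC is recorded. Two comparison modes:
#' `"predictions"` (default, the denoising reading) scores the perturbed
#' run's probabilities on the reference run's predicted edges versus an
#' equal-sized sample of non-predicted pairs; `"heldout"` (the
#' edge-recovery reading) scores the deleted edges themselves versus
#' sampled never-present non-edges.
#'
#' @param expr an [expression_matrix].
#' @param A_c spatial graph; `A_g` gene graph.
#' @param A_g gene graph.
#' @param ratios deletion ratios in `[0, 1)`.
#' @param n_reps replicates per ratio (default 30, the conventional repeat
#'   count; reduce for quick runs).
#' @param hyperparams training hyperparameters.
#' @param base_seed master seed; every replicate's seed derives from it and
#'   is returned, making the whole protocol reproducible.
#' @param compare `"predictions"` or `"heldout"` (see above).
#' @param cutoff binarization cutoff for the reference predictions.
#' @return a `robustness_result` list with the `levels x n_reps` AUC
#'   matrix and per-replicate seeds.
#' @export
robustness_remove <- function(expr, A_c, A_g, ratios = c(0.1, 0.3, 0.5),
                              n_reps = 30L,
                              hyperparams = default_hyperparams(),
                              base_seed = 1L,
                              compare = c("predictions", "heldout"),
                              cutoff = 0.5) {
  compare <- match.arg(compare)
  if (any(ratios < 0 | ratios >= 1)) stop("ratios must be in [0, 1)")
  robustness_run(expr, A_c, A_g, ratios, n_reps, hyperparams, base_seed,
                 "remove", compare, cutoff)
}

#' Robustness to fake spatial edges
#'
#' For each multiplier and replicate, `multiplier x` the current undirected
#' edge count of false edges is added between uniformly sampled
#' non-adjacent cell pairs (never duplicating existing edges or the
#' diagonal), the model is retrained, and the perturbed run's predictions
#' are scored against the reference run's predictions by AUC.
#'
#' @inheritParams robustness_remove
#' @param multipliers nonnegative multiples of the true edge count to add.
#' @return a `robustness_result` list.
#' @export
robustness_fake <- function(expr, A_c, A_g, multipliers = c(1, 3, 5),
                            n_reps = 30L,
                            hyperparams = default_hyperparams(),
                            base_seed = 1L, cutoff = 0.5) {
  if (any(multipliers < 0)) stop("multipliers must be nonnegative")
  robustness_run(expr, A_c, A_g, multipliers, n_reps, hyperparams,
                 base_seed, "fake", "predictions", cutoff)
}

#' @export
print.robustness_result <- function(x, ...) {
  med <- apply(x$auc, 1, stats::median)
  cat(sprintf("robustness_result (%s, %d reps): median AUC by level\n",
              x$scenario, x$n_replicates))
  print(round(med, 4))
  invisible(x)
}
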