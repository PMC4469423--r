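#' Infer a signed co-regulation network from an expression matrix
#'
#' Evaluates the crossed dependence test once for every unordered gene pair
#' and assembles the declared edges into a [coreg_graph]. Every gene of the
#' panel is a vertex, including genes with no declared partner. Each pair's
#' permutation arm is seeded deterministically from the configuration's
#' master seed and the two gene names, so the result is independent of gene
#' ordering, sample ordering and evaluation order, and identical to running
#' [pair_dependence] pair by pair. All pairs are dispatched to the
#' permutation kernel in one batch call.
#'
#' @param em An [expression_matrix] with at least 2 genes and 8 samples
#'   (below 8 samples rank and entropy statistics are meaningless, so the
#'   floor is a hard error).
#' @param config An [analysis_config].
#' @return List with `graph` (a [coreg_graph]) and `results` (data frame of
#'   per-pair statistics: `gene_a`, `gene_b`, `rho`, `p_spearman`,
#'   `mi_bits`, `p_mi`, `edge`, `sign`).
#' @export
infer_network <- function(em, config = analysis_config()) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(config, "analysis_config"))
  genes <- em$gene_names
  n <- nrow(em$values)
  if (length(genes) < 2)
    stop_validation("need at least 2 genes to infer a network")
  if (n < 8)
    stop_degeneracy(sprintf(
      "need at least 8 samples to infer a network (got %d)", n))

  binned <- lapply(genes, function(g) discretize(em$values[, g], config$n_bins))
  labels <- vapply(binned, function(b) b$labels, integer(n))
  nbins <- vapply(binned, function(b) b$n_bins, integer(1))
  pairs <- utils::combn(seq_along(genes), 2)
  pi <- pairs[1, ]; pj <- pairs[2, ]
  seeds <- vapply(seq_along(pi), function(k) {
    pair_seed(config$master_seed, genes[pi[k]], genes[pj[k]])
  }, integer(1))

  mi <- mi_perm_batch_cpp(labels, nbins, pi, pj, seeds,
                          config$n_permutations)
  p_mi <- mi_pvalues(mi$count_ge, mi$mi_obs, mi$surrogate_mean,
                     mi$surrogate_sd, config$n_permutations,
                     config$pvalue_mode)$p

  # Spearman arm, vectorized over the rank-transformed columns; constant
  # genes have no defined rank correlation and never support an edge.
  degen <- apply(em$values, 2, function(v) length(unique(v)) < 2)
  rk <- apply(em$values, 2, rank)
  rho_mat <- suppressWarnings(cor(rk))
  rho <- rho_mat[cbind(pi, pj)]
  pair_degen <- degen[pi] | degen[pj]
  rho[pair_degen] <- 0
  rho <- pmax(-1, pmin(1, rho))
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p_sp <- ifelse(abs(rho) == 1, 0, 2 * pt(-abs(tval), df = n - 2))
  p_sp[pair_degen] <- 1

  edge <- (p_sp <= config$alpha_spearman) & (p_mi < config$alpha_mi) &
    !pair_degen
  sign <- ifelse(!edge, "none", ifelse(rho > 0, "positive", "negative"))
  results <- data.frame(gene_a = genes[pi], gene_b = genes[pj],
                        rho = rho, p_spearman = p_sp,
                        mi_bits = mi$mi_obs, p_mi = p_mi,
                        edge = edge, sign = sign,
                        stringsAsFactors = FALSE)
  edges <- results[results$edge, c("gene_a", "gene_b", "sign"), drop = FALSE]
  list(graph = coreg_graph(genes, edges), results = results)
}
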