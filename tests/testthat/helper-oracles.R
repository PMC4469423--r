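# Independent oracles and fixture builders used across the suite.

# Direct plug-in MI: sum over the joint bin table of
# p_ij * log2(p_ij / (p_i p_j)), independent of the entropy-identity path.
mi_direct <- function(x, y, n_bins = "auto") {
  bx <- discretize(x, n_bins)
  by <- discretize(y, n_bins)
  tab <- table(factor(bx$labels, levels = 0:(bx$n_bins - 1)),
               factor(by$labels, levels = 0:(by$n_bins - 1)))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  as.numeric(s)
}

# All permutations of a vector (for exhaustive permutation-null checks).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# Exact upper-tail proportion of the MI permutation null by enumeration.
exact_mi_tail <- function(x, y, n_bins = "auto") {
  mi_obs <- mutual_information(x, y, n_bins)
  perms <- all_perms(seq_along(y))
  hits <- vapply(perms, function(idx) {
    mutual_information(x, y[idx], n_bins) >= mi_obs - 1e-12
  }, logical(1))
  mean(hits)
}

# Random signed graph over a fixed vertex set.
random_signed_graph <- function(vertices, p_edge = 0.3) {
  pairs <- utils::combn(vertices, 2)
  keep <- runif(ncol(pairs)) < p_edge
  if (!any(keep)) return(coreg_graph(vertices))
  coreg_graph(vertices, data.frame(
    gene_a = pairs[1, keep], gene_b = pairs[2, keep],
    sign = sample(c("positive", "negative"), sum(keep), replace = TRUE),
    stringsAsFactors = FALSE))
}

make_em <- function(values, ids = NULL, genes = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(ncol(values)))
  expression_matrix(values, sample_ids = ids, gene_names = genes,
                    allow_negative = TRUE)
}

write_temp_table <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
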