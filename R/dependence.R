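#' Spearman rank correlation test
#'
#' Rank correlation with average ranks for ties and a two-sided p-value from
#' the t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' n - 2 degrees of freedom. A constant input has no defined rank
#' correlation; the function then returns `rho = 0`, `p = 1` and sets the
#' `degenerate` flag (with a warning).
#'
#' @param x,y Numeric vectors of equal length >= 4, finite values.
#' @return List with `rho` (in \[-1, 1\]), `p` (two-sided) and `degenerate`.
#' @examples
#' spearman_dependence(1:5, c(2, 1, 4, 3, 5))$rho  # 0.8
#' @export
spearman_dependence <- function(x, y) {
  if (length(x) != length(y))
    stop_validation("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop_validation("need at least 4 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_validation("values must be finite")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: Spearman correlation undefined, returning rho = 0")
    return(list(rho = 0, p = 1, degenerate = TRUE))
  }
  rho <- cor(rank(x), rank(y))
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, degenerate = FALSE)
}

#' Discretize a continuous variable into equal-width bins
#'
#' Bins span the observed range `[min(x), max(x)]`; the maximum falls in the
#' last bin. `"auto"` uses `ceiling(log2(n)) + 1` bins (Sturges' rule),
#' capped so that each marginal bin averages at least 8 samples (and never
#' fewer than 2 bins): plug-in entropies on a Sturges grid leave the joint
#' table nearly empty below about 60 samples, which destroys the power of
#' the MI permutation test. At n = 118 the rule gives 8 bins. A constant
#' vector collapses to a single bin.
#'
#' @param x Numeric vector of finite values, length >= 2.
#' @param n_bins Positive integer or `"auto"`.
#' @return Object of class `binned_variable`: integer `labels` in
#'   `[0, n_bins)`, the bin count `n_bins`, and the `bin_edges`.
#' @export
discretize <- function(x, n_bins = "auto") {
  if (length(x) < 2) stop_validation("need at least 2 values to discretize")
  if (any(!is.finite(x))) stop_validation("values must be finite")
  lo <- min(x); hi <- max(x)
  if (lo == hi) {
    return(structure(list(labels = rep(0L, length(x)), n_bins = 1L,
                          bin_edges = c(lo - 0.5, hi + 0.5)),
                     class = "binned_variable"))
  }
  nb <- if (identical(n_bins, "auto")) {
    max(2, min(ceiling(log2(length(x))) + 1, length(x) %/% 8))
  } else {
    as.integer(n_bins)
  }
  if (nb < 1) stop_validation("n_bins must be >= 1")
  edges <- seq(lo, hi, length.out = nb + 1)
  labels <- findInterval(x, edges, rightmost.closed = TRUE) - 1L
  structure(list(labels = as.integer(labels), n_bins = as.integer(nb),
                 bin_edges = edges),
            class = "binned_variable")
}

#' Plug-in marginal entropy (bits)
#'
#' Shannon entropy `H(X) = -sum_i P(x_i) log2 P(x_i)` of the empirical bin
#' frequencies; empty bins contribute nothing.
#'
#' @param b A `binned_variable` from [discretize].
#' @return Entropy in bits, >= 0.
#' @export
marginal_entropy <- function(b) {
  stopifnot(inherits(b, "binned_variable"))
  counts <- tabulate(b$labels + 1L, nbins = b$n_bins)
  entropy_from_counts(counts)
}

#' Plug-in joint entropy (bits)
#'
#' Shannon entropy of the empirical joint distribution of two binned
#' variables observed on the same samples.
#'
#' @param a,b `binned_variable` objects of equal length.
#' @return Joint entropy in bits, >= 0.
#' @export
joint_entropy <- function(a, b) {
  stopifnot(inherits(a, "binned_variable"), inherits(b, "binned_variable"))
  if (length(a$labels) != length(b$labels))
    stop_validation("binned variables must have equal length")
  cell <- a$labels * b$n_bins + b$labels
  counts <- tabulate(cell + 1L, nbins = a$n_bins * b$n_bins)
  entropy_from_counts(counts)
}

#' @noRd
entropy_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Mutual information between two continuous variables (bits)
#'
#' Both variables are discretized with [discretize] and the plug-in identity
#' `M(X, Y) = H(X) + H(Y) - H(X, Y)` is evaluated on that shared binning.
#' Tiny negative floating-point residue is clamped to 0.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param n_bins Bins per variable, or `"auto"` (see [discretize]).
#' @return Mutual information in bits, >= 0.
#' @export
mutual_information <- function(x, y, n_bins = "auto") {
  if (length(x) != length(y))
    stop_validation("x and y must have equal length")
  if (length(x) < 4) stop_validation("need at least 4 paired observations")
  bx <- discretize(x, n_bins)
  by <- discretize(y, n_bins)
  mi <- marginal_entropy(bx) + marginal_entropy(by) - joint_entropy(bx, by)
  max(mi, 0)
}

#' Permutation significance test for mutual information
#'
#' Builds the null distribution of MI by shuffling the values of `y` only
#' (random row permutations), which preserves both marginal distributions.
#' The empirical p-value is `(1 + #\{MI_k >= MI_obs\}) / (n_permutations + 1)`;
#' the z-test variant assumes normally distributed surrogate MI and returns
#' the one-sided upper-tail probability from the surrogate mean and standard
#' deviation (falling back to the empirical p-value, with a warning, when
#' the surrogate standard deviation is zero).
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_permutations Number of shuffles, >= 100.
#' @param mode `"empirical"` or `"ztest"`.
#' @param seed Integer seed for the shuffles.
#' @param n_bins Bins per variable, or `"auto"`.
#' @return List with `p`, `mi_obs` (bits), `surrogate_mean`, `surrogate_sd`
#'   and the `mode` actually used.
#' @export
mi_permutation_pvalue <- function(x, y, n_permutations = 20000,
                                  mode = c("empirical", "ztest"),
                                  seed = 1L, n_bins = "auto") {
  mode <- match.arg(mode)
  if (length(x) != length(y))
    stop_validation("x and y must have equal length")
  if (n_permutations < 100)
    stop_validation("n_permutations must be >= 100")
  bx <- discretize(x, n_bins)
  by <- discretize(y, n_bins)
  res <- mi_perm_cpp(bx$labels, by$labels, bx$n_bins, by$n_bins,
                     as.integer(n_permutations), as.integer(seed))
  pv <- mi_pvalues(res$count_ge, res$mi_obs, res$surrogate_mean,
                   res$surrogate_sd, n_permutations, mode)
  list(p = pv$p, mi_obs = res$mi_obs, surrogate_mean = res$surrogate_mean,
       surrogate_sd = res$surrogate_sd, mode = pv$mode)
}

# Turns surrogate summaries into p-values (vectorized). In ztest mode a
# zero surrogate standard deviation falls back to the empirical p-value.
#' @noRd
mi_pvalues <- function(count_ge, mi_obs, surr_mean, surr_sd,
                       n_permutations, mode) {
  p_emp <- (1 + count_ge) / (n_permutations + 1)
  if (mode == "empirical") return(list(p = p_emp, mode = "empirical"))
  zero <- surr_sd == 0
  if (any(zero))
    warning("zero surrogate standard deviation: falling back to empirical p-value")
  p <- ifelse(zero, p_emp,
              pnorm(mi_obs, mean = surr_mean, sd = surr_sd,
                    lower.tail = FALSE))
  list(p = p, mode = if (all(zero)) "empirical" else "ztest")
}

#' Crossed dependence test for one gene pair
#'
#' Runs both arms — the Spearman rank test and the MI permutation test — and
#' declares an edge when `p_spearman <= alpha_spearman` and
#' `p_mi < alpha_mi`. The edge sign is the sign of the Spearman correlation.
#'
#' @param x,y Expression vectors of the two genes over the same samples.
#' @param config An [analysis_config].
#' @param gene_a,gene_b Gene names carried into the result.
#' @param seed Seed for the permutation arm; defaults to a deterministic
#'   sub-seed from `config$master_seed` and the (sorted) gene names.
#' @return Object of class `dependence_result`: `gene_a`, `gene_b`, `rho`,
#'   `p_spearman`, `mi_bits`, `p_mi`, `edge`, `sign` (`"positive"`,
#'   `"negative"` or `"none"`).
#' @export
pair_dependence <- function(x, y, config = analysis_config(),
                            gene_a = "X", gene_b = "Y", seed = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(seed)) seed <- pair_seed(config$master_seed, gene_a, gene_b)
  sp <- spearman_dependence(x, y)
  mi <- mi_permutation_pvalue(x, y, n_permutations = config$n_permutations,
                              mode = config$pvalue_mode, seed = seed,
                              n_bins = config$n_bins)
  edge <- (sp$p <= config$alpha_spearman) && (mi$p < config$alpha_mi) &&
    !sp$degenerate
  sign <- if (!edge) "none" else if (sp$rho > 0) "positive" else "negative"
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 rho = sp$rho, p_spearman = sp$p,
                 mi_bits = mi$mi_obs, p_mi = mi$p,
                 edge = edge, sign = sign),
            class = "dependence_result")
}

#' @export
print.dependence_result <- function(x, ...) {
  cat(sprintf("%s -- %s: rho = %.3f (p = %.3g), MI = %.3f bits (p = %.3g) -> %s\n",
              x$gene_a, x$gene_b, x$rho, x$p_spearman, x$mi_bits, x$p_mi,
              if (x$edge) paste0("edge (", x$sign, ")") else "no edge"))
  invisible(x)
}

#' Collect dependence results into a table
#'
#' @param results List of `dependence_result` objects.
#' @return Data frame with one row per gene pair, suitable for
#'   [utils::write.table] export.
#' @export
dependence_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(gene_a = r$gene_a, gene_b = r$gene_b, rho = r$rho,
               p_spearman = r$p_spearman, mi_bits = r$mi_bits,
               p_mi = r$p_mi, edge = r$edge, sign = r$sign,
               stringsAsFactors = FALSE)
  }))
}
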