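#' Analysis configuration
#'
#' Collects the tunable parameters of the crossed dependence test and its
#' permutation calibration. An edge between two genes is declared when the
#' Spearman test p-value is `<= alpha_spearman` *and* the mutual information
#' permutation p-value is `< alpha_mi`.
#'
#' @param alpha_spearman Significance level of the Spearman arm, in (0, 1).
#' @param alpha_mi Significance level of the mutual information arm, in (0, 1).
#' @param n_permutations Number of random shuffles of one variable used to
#'   build the null distribution of mutual information. At least 100.
#' @param pvalue_mode `"empirical"` counts the proportion of surrogate MI
#'   values reaching the observed one (with a +1 correction, so the smallest
#'   attainable p-value is `1/(n_permutations + 1)`); `"ztest"` assumes the
#'   surrogate MI values are normal and returns a one-sided upper-tail
#'   p-value from their mean and standard deviation.
#' @param n_bins Number of equal-width bins per variable used by the entropy
#'   estimator, or `"auto"` for `ceiling(log2(n)) + 1` bins at sample size n.
#' @param master_seed Integer master seed. Each gene pair receives its own
#'   deterministic sub-seed derived from the master seed and the two gene
#'   names, so results do not depend on evaluation order.
#' @return An object of class `analysis_config` (a named list).
#' @examples
#' cfg <- analysis_config(n_permutations = 500)
#' cfg$alpha_mi
#' @export
analysis_config <- function(alpha_spearman = 0.05,
                            alpha_mi = 0.01,
                            n_permutations = 20000,
                            pvalue_mode = c("empirical", "ztest"),
                            n_bins = "auto",
                            master_seed = 1L) {
  pvalue_mode <- match.arg(pvalue_mode)
  if (!is.numeric(alpha_spearman) || length(alpha_spearman) != 1 ||
      alpha_spearman <= 0 || alpha_spearman >= 1)
    stop_validation("alpha_spearman must be a single number in (0, 1)")
  if (!is.numeric(alpha_mi) || length(alpha_mi) != 1 ||
      alpha_mi <= 0 || alpha_mi >= 1)
    stop_validation("alpha_mi must be a single number in (0, 1)")
  if (!is.numeric(n_permutations) || length(n_permutations) != 1 ||
      n_permutations < 100 || n_permutations != round(n_permutations))
    stop_validation("n_permutations must be a single integer >= 100")
  if (!identical(n_bins, "auto") &&
      (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 1 ||
       n_bins != round(n_bins)))
    stop_validation("n_bins must be a positive integer or \"auto\"")
  if (!is.numeric(master_seed) || length(master_seed) != 1 ||
      master_seed != round(master_seed))
    stop_validation("master_seed must be a single integer")
  structure(list(alpha_spearman = alpha_spearman,
                 alpha_mi = alpha_mi,
                 n_permutations = as.integer(n_permutations),
                 pvalue_mode = pvalue_mode,
                 n_bins = if (identical(n_bins, "auto")) "auto"
                          else as.integer(n_bins),
                 master_seed = as.integer(master_seed)),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  alpha (Spearman arm): %g\n", x$alpha_spearman))
  cat(sprintf("  alpha (MI arm):       %g\n", x$alpha_mi))
  cat(sprintf("  permutations:         %d (%s p-value)\n",
              x$n_permutations, x$pvalue_mode))
  cat(sprintf("  bins:                 %s\n",
              if (identical(x$n_bins, "auto")) "auto (Sturges)"
              else as.character(x$n_bins)))
  cat(sprintf("  master seed:          %d\n", x$master_seed))
  invisible(x)
}
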