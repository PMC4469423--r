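#' Default gene panel of the simulator
#'
#' Estrogen and growth-factor receptors plus metastasis markers typically
#' assayed together on breast-tumor qPCR panels; `"ERa36"` is the default
#' candidate classifier.
#'
#' @return Character vector of 11 gene names.
#' @export
default_gene_panel <- function() {
  c("ERa66", "ERa36", "GPER", "EGFR", "HER2",
    "SNAIL1", "CXCR4", "RANKL", "DDB2", "VIM", "MMP9")
}

#' @noRd
check_corr_matrix <- function(R, what) {
  if (!isSymmetric(unname(R), tol = 1e-10))
    stop_validation(paste0(what, " must be symmetric"))
  if (any(abs(diag(R) - 1) > 1e-10))
    stop_validation(paste0(what, " must have unit diagonal"))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_validation(sprintf("%s is not positive semidefinite (eigenvalue %.6g)",
                            what, min(ev)))
  invisible(R)
}

# Default two-regime dependence structure over the 10 non-classifier genes,
# following the panel's biological grouping: in the low-classifier regime
# the receptor / ER-status module (ERa66, GPER, EGFR, HER2, DDB2) is
# co-regulated (equicorrelated block, 10 positive edges) and the metastasis
# markers are independent; in the high-classifier regime the receptor
# module dissolves and the metastatic-marker module (SNAIL1, CXCR4, RANKL,
# VIM, MMP9) is co-regulated instead. The planted edge sets are disjoint,
# so a clean split at the regime boundary maximizes the number of edges
# present on exactly one side, while mixed subgroups dilute both modules
# toward zero correlation. Equicorrelated blocks are positive definite
# (eigenvalues 1 + 4s, 1 - s). The default strength 0.9 (latent scale,
# attenuated to ~0.85 by the default observation noise) gives per-edge
# detection power of about 0.8 at the smallest subgroup of interest (~24
# samples), which the planted-structure recovery study requires; a much
# stronger contrast saturates the distance curve into a flat plateau and a
# much weaker one leaves the small subgroup's module undetectable.
#' @noRd
default_regime_matrices <- function(genes, strength = 0.9) {
  R_low <- diag(length(genes)); dimnames(R_low) <- list(genes, genes)
  R_high <- R_low
  fill_block <- function(M, members) {
    for (a in members) for (b in members) if (a != b) M[a, b] <- strength
    M
  }
  receptors <- c("ERa66", "GPER", "EGFR", "HER2", "DDB2")
  markers <- c("SNAIL1", "CXCR4", "RANKL", "VIM", "MMP9")
  if (all(receptors %in% genes)) R_low <- fill_block(R_low, receptors)
  if (all(markers %in% genes)) R_high <- fill_block(R_high, markers)
  list(low = R_low, high = R_high)
}

#' Simulation configuration
#'
#' Parameters of the synthetic qPCR cohort generator. Defaults emulate a
#' retrospective breast-tumor cohort: 118 samples, an 11-gene panel,
#' relative expression spanning 0-20, a right-skewed classifier-gene
#' distribution with roughly 8.5% non-detects, a planted regime change at
#' classifier value 8.5 placing about 22% of expressing samples in the high
#' group, and a strong two-module dependence contrast between regimes
#' (latent correlation 0.9, mildly attenuated by observation noise).
#'
#' @param n_samples Cohort size (default 118).
#' @param gene_names Gene panel (default [default_gene_panel()]).
#' @param classifier_gene Gene whose value selects the dependence regime.
#' @param planted_threshold Regime boundary on the expression scale; must
#'   lie strictly inside `expression_range`.
#' @param regime_low_corr,regime_high_corr Correlation matrices over the
#'   non-classifier genes (symmetric, unit diagonal, positive semidefinite);
#'   `NULL` uses the default two-module contrast.
#' @param expression_range Range of the expression scale (default `c(0, 20)`).
#' @param nondetect_fraction Expected fraction of samples with classifier
#'   value 0 ("not detected"; default 10/118).
#' @param noise_sd Standard deviation of independent latent noise added to
#'   each non-classifier gene before mapping to the expression scale
#'   (default 0.25 on the unit latent scale; attenuates the planted
#'   correlation r to r / (1 + noise_sd^2)).
#' @param classifier_beta Beta shape parameters of the classifier-gene
#'   distribution over `expression_range` (default `c(1.6, 3.94)`, which
#'   puts 78% of the mass below 8.5 on the 0-20 scale).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 118,
                              gene_names = default_gene_panel(),
                              classifier_gene = "ERa36",
                              planted_threshold = 8.5,
                              regime_low_corr = NULL,
                              regime_high_corr = NULL,
                              expression_range = c(0, 20),
                              nondetect_fraction = 10 / 118,
                              noise_sd = 0.25,
                              classifier_beta = c(1.6, 3.94),
                              seed = 1L) {
  if (!classifier_gene %in% gene_names)
    stop_validation("classifier_gene must be one of gene_names")
  if (anyDuplicated(gene_names)) stop_validation("duplicated gene names")
  if (length(expression_range) != 2 ||
      expression_range[1] >= expression_range[2])
    stop_validation("expression_range must be an increasing pair")
  if (planted_threshold <= expression_range[1] ||
      planted_threshold >= expression_range[2])
    stop_validation("planted_threshold must lie strictly inside expression_range")
  if (nondetect_fraction < 0 || nondetect_fraction >= 1)
    stop_validation("nondetect_fraction must be in [0, 1)")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  others <- setdiff(gene_names, classifier_gene)
  if (is.null(regime_low_corr) || is.null(regime_high_corr)) {
    defaults <- default_regime_matrices(others)
    if (is.null(regime_low_corr)) regime_low_corr <- defaults$low
    if (is.null(regime_high_corr)) regime_high_corr <- defaults$high
  }
  for (nm in c("regime_low_corr", "regime_high_corr")) {
    R <- get(nm)
    if (!is.matrix(R) || nrow(R) != length(others) ||
        is.null(rownames(R)) || !setequal(rownames(R), others))
      stop_validation(sprintf(
        "%s must be a named square matrix over the non-classifier genes", nm))
    check_corr_matrix(R[others, others], nm)
  }
  structure(list(n_samples = as.integer(n_samples), gene_names = gene_names,
                 classifier_gene = classifier_gene,
                 planted_threshold = planted_threshold,
                 regime_low_corr = regime_low_corr[others, others],
                 regime_high_corr = regime_high_corr[others, others],
                 expression_range = expression_range,
                 nondetect_fraction = nondetect_fraction,
                 noise_sd = noise_sd, classifier_beta = classifier_beta,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Named simulation presets
#'
#' `"two-regime"` is the default configuration (planted dependence contrast
#' across the classifier threshold); `"single-regime"` applies the
#' low-regime dependence structure to all samples (no classifier signal,
#' but real co-regulation); `"null"` makes all genes independent.
#'
#' @param preset One of `"two-regime"`, `"single-regime"`, `"null"`.
#' @param ... Further arguments passed to [simulation_config].
#' @return A `simulation_config`.
#' @export
simulation_preset <- function(preset = c("two-regime", "single-regime", "null"),
                              ...) {
  preset <- match.arg(preset)
  cfg <- simulation_config(...)
  if (preset == "single-regime") {
    cfg$regime_high_corr <- cfg$regime_low_corr
  } else if (preset == "null") {
    id <- diag(nrow(cfg$regime_low_corr))
    dimnames(id) <- dimnames(cfg$regime_low_corr)
    cfg$regime_low_corr <- id
    cfg$regime_high_corr <- id
  }
  cfg
}

#' @noRd
planted_edges <- function(R) {
  genes <- rownames(R)
  out <- data.frame(gene_a = character(), gene_b = character(),
                    sign = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(R) - 1)) {
    for (j in seq(i + 1, nrow(R))) {
      if (R[i, j] != 0) {
        ga <- min(genes[i], genes[j]); gb <- max(genes[i], genes[j])
        out <- rbind(out, data.frame(
          gene_a = ga, gene_b = gb,
          sign = if (R[i, j] > 0) "positive" else "negative",
          stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Simulate a synthetic qPCR cohort
#'
#' Draws the classifier gene from a scaled Beta distribution over the
#' expression range (a `nondetect_fraction` of samples is set to 0). The
#' non-classifier genes come from a Gaussian copula: a latent multivariate
#' normal with the regime correlation matrix chosen by each sample's
#' classifier value relative to the planted threshold, plus independent
#' latent noise, mapped monotonically (probability-integral transform) onto
#' the expression range. The monotone map preserves the rank structure that
#' the Spearman and binning statistics consume while keeping every marginal
#' inside the expression range.
#'
#' @param config A [simulation_config].
#' @return List with `matrix` (an [expression_matrix]) and `truth` (class
#'   `simulation_truth`): per-sample `regime` labels, the
#'   `planted_threshold`, and the planted signed edge lists `edges_low`,
#'   `edges_high`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  lo <- config$expression_range[1]; hi <- config$expression_range[2]
  others <- setdiff(config$gene_names, config$classifier_gene)

  cls <- lo + (hi - lo) * rbeta(n, config$classifier_beta[1],
                                config$classifier_beta[2])
  nondetect <- runif(n) < config$nondetect_fraction
  cls[nondetect] <- 0
  regime <- ifelse(cls >= config$planted_threshold, "high", "low")

  vals <- matrix(NA_real_, nrow = n, ncol = length(others),
                 dimnames = list(NULL, others))
  tot_sd <- sqrt(1 + config$noise_sd^2)
  for (rg in c("low", "high")) {
    idx <- which(regime == rg)
    if (!length(idx)) next
    R <- if (rg == "low") config$regime_low_corr else config$regime_high_corr
    z <- MASS::mvrnorm(length(idx), mu = rep(0, length(others)), Sigma = R)
    z <- matrix(z, ncol = length(others))
    z <- z + matrix(rnorm(length(z), sd = config$noise_sd), nrow = nrow(z))
    vals[idx, ] <- lo + (hi - lo) * pnorm(z / tot_sd)
  }
  full <- cbind(vals, cls)
  colnames(full) <- c(others, config$classifier_gene)
  full <- full[, config$gene_names, drop = FALSE]
  ids <- sprintf("S%03d", seq_len(n))
  em <- expression_matrix(full, sample_ids = ids,
                          gene_names = config$gene_names)
  truth <- structure(list(regime = stats::setNames(regime, ids),
                          planted_threshold = config$planted_threshold,
                          edges_low = planted_edges(config$regime_low_corr),
                          edges_high = planted_edges(config$regime_high_corr)),
                     class = "simulation_truth")
  list(matrix = em, truth = truth)
}

#' Simulate an independent pair of variables
#'
#' Two independent standard-normal draws, used by type-I-error studies of
#' the dependence tests.
#'
#' @param n Sample size, >= 8.
#' @param seed Integer seed.
#' @return List with numeric vectors `x` and `y`.
#' @export
simulate_null_pair <- function(n, seed = 1L) {
  if (n < 8) stop_validation("n must be >= 8")
  set.seed(seed)
  list(x = rnorm(n), y = rnorm(n))
}

#' Simulate a correlated bivariate-normal pair
#'
#' Used by power studies of the crossed dependence test.
#'
#' @param n Sample size, >= 8.
#' @param rho Latent correlation in (-1, 1).
#' @param seed Integer seed.
#' @return List with numeric vectors `x` and `y`.
#' @export
simulate_correlated_pair <- function(n, rho, seed = 1L) {
  if (n < 8) stop_validation("n must be >= 8")
  if (abs(rho) >= 1) stop_validation("rho must be in (-1, 1)")
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y)
}
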