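#' Keep only samples expressing a gene
#'
#' A value of 0 on the relative-expression scale means "not detected";
#' classifier threshold scans are restricted to samples with strictly
#' positive expression of the candidate gene.
#'
#' @param em An [expression_matrix].
#' @param gene Gene whose expression gates the samples.
#' @return An [expression_matrix] of the retained samples, with attribute
#'   `n_excluded_nonexpressing` giving the number dropped. Warns when no
#'   sample expresses the gene.
#' @export
filter_expressing <- function(em, gene) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!gene %in% em$gene_names)
    stop_validation(sprintf("gene '%s' not found; available genes: %s",
                            gene, paste(em$gene_names, collapse = ", ")))
  keep <- em$values[, gene] > 0
  if (!any(keep)) warning(sprintf("no sample expresses '%s'", gene))
  out <- em_subset(em, keep)
  attr(out, "n_excluded_nonexpressing") <- sum(!keep)
  out
}

#' Split samples by an expression threshold
#'
#' Samples with expression of `gene` at or above `t` form the high group,
#' the rest the low group; the partition is exhaustive and disjoint.
#'
#' @param em An [expression_matrix].
#' @param gene Gene whose expression is thresholded.
#' @param t Threshold on the expression scale.
#' @return List with `low` and `high` [expression_matrix] objects.
#' @export
split_by_threshold <- function(em, gene, t) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!gene %in% em$gene_names)
    stop_validation(sprintf("gene '%s' not found; available genes: %s",
                            gene, paste(em$gene_names, collapse = ", ")))
  high <- em$values[, gene] >= t
  list(low = em_subset(em, !high), high = em_subset(em, high))
}

#' Threshold scan of a candidate classifier gene
#'
#' Sweeps a grid of candidate thresholds on the expression of `gene`
#' (restricted to expressing samples, see [filter_expressing]). At every
#' admissible threshold the cohort is split in two ([split_by_threshold]),
#' one network is inferred per subgroup with identical configuration, and
#' the integer distance between the two networks is recorded. The threshold
#' maximizing the distance — the split producing the most different
#' co-regulation structures — is reported; ties go to the smallest
#' threshold and are flagged.
#'
#' With `candidates = "step"` the grid runs from the minimum observed
#' expressing value plus `step` up to the maximum observed value, in
#' increments of `step` anchored at the data minimum. With
#' `candidates = "observed-midpoints"` the candidates are the midpoints
#' between consecutive distinct observed values.
#'
#' @param em An [expression_matrix].
#' @param gene Candidate classifier gene.
#' @param config An [analysis_config]; `n_permutations` may be reduced for
#'   exploratory scans.
#' @param step Grid step on the expression scale (default 0.5).
#' @param min_group_size Smallest admissible subgroup (default 12); grid
#'   points violating it are kept in the curve but marked unevaluated.
#' @param candidates `"step"` or `"observed-midpoints"`.
#' @return Object of class `scan_result`: `gene`, `curve` (data frame with
#'   `threshold`, `n_low`, `n_high`, `distance`, `evaluated`),
#'   `best_threshold`, `best_distance`, `n_excluded_nonexpressing`, `tie`.
#' @export
threshold_scan <- function(em, gene, config = analysis_config(),
                           step = 0.5, min_group_size = 12,
                           candidates = c("step", "observed-midpoints")) {
  candidates <- match.arg(candidates)
  if (step <= 0) stop_validation("step must be > 0")
  if (min_group_size < 8)
    stop_validation("min_group_size must be >= 8 (network inference floor)")
  expressing <- filter_expressing(em, gene)
  n_excl <- attr(expressing, "n_excluded_nonexpressing")
  v <- expressing$values[, gene]
  if (length(v) < 2 * min_group_size)
    stop_degeneracy(sprintf(
      "only %d expressing samples; need at least 2 x min_group_size = %d",
      length(v), 2 * min_group_size))
  if (candidates == "step") {
    grid <- seq(min(v) + step, max(v), by = step)
  } else {
    sv <- sort(unique(v))
    grid <- (sv[-1] + sv[-length(sv)]) / 2
  }
  if (!length(grid)) stop_degeneracy("no admissible split: empty candidate grid")
  curve <- data.frame(threshold = grid, n_low = NA_integer_,
                      n_high = NA_integer_, distance = NA_integer_,
                      evaluated = FALSE)
  for (i in seq_along(grid)) {
    n_high <- sum(v >= grid[i])
    n_low <- length(v) - n_high
    curve$n_low[i] <- n_low
    curve$n_high[i] <- n_high
    if (n_low < min_group_size || n_high < min_group_size) next
    parts <- split_by_threshold(expressing, gene, grid[i])
    g_low <- infer_network(parts$low, config)$graph
    g_high <- infer_network(parts$high, config)$graph
    curve$distance[i] <- graph_distance(g_low, g_high)
    curve$evaluated[i] <- TRUE
  }
  if (!any(curve$evaluated))
    stop_degeneracy("no admissible split: every candidate violates min_group_size")
  ev <- curve[curve$evaluated, , drop = FALSE]
  best_d <- max(ev$distance)
  at_max <- ev$threshold[ev$distance == best_d]
  structure(list(gene = gene, curve = curve,
                 best_threshold = min(at_max),
                 best_distance = as.integer(best_d),
                 n_excluded_nonexpressing = n_excl,
                 tie = length(at_max) > 1),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Threshold scan on '%s'\n", x$gene))
  cat(sprintf("  %d candidate thresholds (%d evaluated), %d non-expressing samples excluded\n",
              nrow(x$curve), sum(x$curve$evaluated), x$n_excluded_nonexpressing))
  cat(sprintf("  best threshold: %g (distance %d%s)\n", x$best_threshold,
              x$best_distance, if (x$tie) ", tie broken toward smallest" else ""))
  invisible(x)
}

#' Plot a scan distance curve
#'
#' Distance between the two subgroup networks as a function of the
#' candidate threshold; unevaluated grid points (subgroup too small) appear
#' as gaps, and the best threshold is marked.
#'
#' @param scan A `scan_result` from [threshold_scan].
#' @param path Optional PNG output path; `NULL` draws on the active device.
#' @export
plot_scan_curve <- function(scan, path = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off())
  }
  cv <- scan$curve
  graphics::plot(cv$threshold, cv$distance, type = "b", pch = 16,
                 xlab = sprintf("%s expression threshold", scan$gene),
                 ylab = "network distance",
                 main = sprintf("Network distance vs %s threshold", scan$gene))
  graphics::abline(v = scan$best_threshold, lty = 2, col = "grey40")
  graphics::mtext(sprintf("best threshold %g (distance %d)",
                          scan$best_threshold, scan$best_distance),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(scan)
}
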