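#' Infer and compare networks for two annotated sample groups
#'
#' Stratifies the cohort by an annotation label (for example hormone
#' receptor status), infers one signed co-regulation network per group with
#' identical configuration, and reports the integer distance between them.
#'
#' @param em An [expression_matrix].
#' @param annotation Data frame with columns `sample_id` and `label` (see
#'   [read_sample_annotation]).
#' @param label_a,label_b The two labels to compare.
#' @param config An [analysis_config].
#' @return List with `graphs` (named list of two [coreg_graph]s), `results`
#'   (named list of per-pair statistics tables), `n` (group sizes),
#'   `distance` and the full `distance_report`.
#' @export
run_stratified_networks <- function(em, annotation, label_a, label_b,
                                    config = analysis_config()) {
  stopifnot(inherits(em, "expression_matrix"))
  miss <- setdiff(annotation$sample_id, em$sample_ids)
  if (length(miss))
    stop_validation(paste0("annotated sample id(s) absent from expression matrix: ",
                           paste(miss, collapse = ", ")))
  groups <- list()
  for (lab in c(label_a, label_b)) {
    ids <- annotation$sample_id[annotation$label == lab]
    if (!length(ids))
      stop_validation(sprintf("no sample carries label '%s'", lab))
    groups[[lab]] <- em_subset(em, match(ids, em$sample_ids))
  }
  nets <- lapply(groups, infer_network, config = config)
  rep <- graph_distance_report(nets[[label_a]]$graph, nets[[label_b]]$graph)
  list(graphs = lapply(nets, `[[`, "graph"),
       results = lapply(nets, `[[`, "results"),
       n = vapply(groups, function(g) nrow(g$values), integer(1)),
       distance = rep$distance,
       distance_report = rep)
}

#' @noRd
write_json_file <- function(x, path) {
  writeLines(jsonlite::toJSON(x, dataframe = "rows", digits = NA,
                              auto_unbox = TRUE, na = "null", pretty = TRUE),
             path)
  invisible(path)
}

#' @noRd
scan_result_payload <- function(scan) {
  list(gene = scan$gene,
       best_threshold = scan$best_threshold,
       best_distance = scan$best_distance,
       n_excluded_nonexpressing = scan$n_excluded_nonexpressing,
       tie = scan$tie,
       curve = scan$curve)
}

#' @noRd
write_graph_bundle <- function(g, dir, stem) {
  for (fmt in c("json", "graphml", "dot")) {
    write_coreg_graph(g, file.path(dir, paste0(stem, ".", fmt)), fmt)
  }
}

#' @noRd
digest_matrix <- function(em) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_expression_table(em, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full three-step classifier study
#'
#' Executes the complete workflow on one cohort: (1) if an annotation is
#' supplied, stratified networks for the two annotation labels and their
#' distance; (2) a threshold scan of the candidate classifier gene; (3)
#' networks of the two subgroups induced by the best threshold, inferred at
#' the full permutation budget. All artifacts (graphs in JSON/GraphML/DOT,
#' per-pair statistics tables, the scan curve, distances, an optional scan
#' plot, and a run manifest recording every numeric setting) are written to
#' `out_dir`. Given the same inputs, configuration and master seed the
#' JSON outputs are reproduced byte for byte.
#'
#' @param em An [expression_matrix].
#' @param classifier_gene Candidate classifier gene.
#' @param config An [analysis_config]; its `n_permutations` is the full
#'   budget used for the final subgroup networks.
#' @param out_dir Output directory (created if needed).
#' @param annotation Optional annotation data frame for step 1.
#' @param label_a,label_b Annotation labels compared in step 1.
#' @param step,min_group_size,candidates Scan parameters, see
#'   [threshold_scan].
#' @param scan_n_permutations Reduced permutation budget used during the
#'   scan sweep (default: the full budget).
#' @param plot Also write a PNG of the scan curve.
#' @return The report bundle as a list (invisibly): manifest, optional
#'   stratified results, scan result, best-split networks and distance.
#' @export
run_full_study <- function(em, classifier_gene, config = analysis_config(),
                           out_dir = ".", annotation = NULL,
                           label_a = NULL, label_b = NULL,
                           step = 0.5, min_group_size = 12,
                           candidates = "step",
                           scan_n_permutations = config$n_permutations,
                           plot = FALSE) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list()

  if (!is.null(annotation)) {
    if (is.null(label_a) || is.null(label_b)) {
      labs <- sort(unique(annotation$label))
      if (length(labs) != 2)
        stop_validation("annotation must have exactly two labels (or pass label_a/label_b)")
      label_a <- labs[1]; label_b <- labs[2]
    }
    strat <- run_stratified_networks(em, annotation, label_a, label_b, config)
    for (lab in c(label_a, label_b)) {
      stem <- paste0("stratified_", gsub("[^A-Za-z0-9+-]", "_", lab))
      write_graph_bundle(strat$graphs[[lab]], out_dir, stem)
      write.table(strat$results[[lab]],
                  file.path(out_dir, paste0(stem, "_stats.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_json_file(list(label_a = label_a, label_b = label_b,
                         n = as.list(strat$n),
                         distance = strat$distance,
                         n_pairs_compared = strat$distance_report$n_pairs_compared,
                         contributions = strat$distance_report$contributions),
                    file.path(out_dir, "stratified_distance.json"))
    bundle$stratified <- strat
  }

  scan_config <- config
  scan_config$n_permutations <- as.integer(scan_n_permutations)
  scan <- threshold_scan(em, classifier_gene, config = scan_config,
                         step = step, min_group_size = min_group_size,
                         candidates = candidates)
  write_json_file(scan_result_payload(scan), file.path(out_dir, "scan.json"))
  if (plot) plot_scan_curve(scan, file.path(out_dir, "scan.png"))
  bundle$scan <- scan

  expressing <- filter_expressing(em, classifier_gene)
  parts <- split_by_threshold(expressing, classifier_gene, scan$best_threshold)
  nets <- lapply(parts, infer_network, config = config)
  for (side in c("low", "high")) {
    stem <- paste0("best_", side)
    write_graph_bundle(nets[[side]]$graph, out_dir, stem)
    write.table(nets[[side]]$results,
                file.path(out_dir, paste0(stem, "_stats.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep <- graph_distance_report(nets$low$graph, nets$high$graph)
  write_json_file(list(threshold = scan$best_threshold,
                       n = list(low = nrow(parts$low$values),
                                high = nrow(parts$high$values)),
                       distance = rep$distance,
                       n_pairs_compared = rep$n_pairs_compared,
                       contributions = rep$contributions),
                  file.path(out_dir, "best_split_distance.json"))
  bundle$best_split <- list(networks = nets, distance_report = rep)

  manifest <- list(tool = "coregscan",
                   version = as.character(packageVersion("coregscan")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   master_seed = config$master_seed,
                   classifier_gene = classifier_gene,
                   config = unclass(config),
                   scan = list(step = step, min_group_size = min_group_size,
                               candidates = candidates,
                               n_permutations = as.integer(scan_n_permutations)),
                   stratification = if (is.null(annotation)) NULL
                                    else list(label_a = label_a, label_b = label_b),
                   input_digest = list(expression = digest_matrix(em)))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  bundle$manifest <- manifest
  invisible(bundle)
}
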