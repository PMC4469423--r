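#' Signed co-regulation graph
#'
#' Undirected graph over a gene panel. Vertices are genes (isolated genes
#' stay in the vertex set); each edge joins two distinct genes and carries a
#' sign, `"positive"` or `"negative"`, the sign of the Spearman correlation
#' that supported it. Edges are stored canonically (endpoints sorted, rows
#' ordered), so two graphs with the same content compare identical.
#'
#' @param vertices Character vector of gene names (no duplicates).
#' @param edges Data frame with columns `gene_a`, `gene_b`, `sign`, or
#'   `NULL` for an edgeless graph.
#' @return Object of class `coreg_graph`.
#' @examples
#' g <- coreg_graph(c("A", "B", "C"),
#'                  data.frame(gene_a = "A", gene_b = "B", sign = "positive"))
#' @export
coreg_graph <- function(vertices, edges = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices))
    stop_validation("duplicated vertex names")
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        sign = character(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene_a = as.character(edges$gene_a),
                        gene_b = as.character(edges$gene_b),
                        sign = as.character(edges$sign),
                        stringsAsFactors = FALSE)
    if (!all(edges$sign %in% c("positive", "negative")))
      stop_validation("edge sign must be 'positive' or 'negative'")
    if (any(edges$gene_a == edges$gene_b))
      stop_validation("self-loops are not allowed")
    if (!all(c(edges$gene_a, edges$gene_b) %in% vertices))
      stop_validation("edge endpoint not in vertex set")
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
    if (anyDuplicated(key))
      stop_validation("parallel edges are not allowed")
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(vertices = vertices, edges = edges), class = "coreg_graph")
}

#' @export
print.coreg_graph <- function(x, ...) {
  cat(sprintf("Co-regulation graph: %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  if (nrow(x$edges)) {
    mark <- ifelse(x$edges$sign == "positive", "+", "-")
    cat(paste0("  ", x$edges$gene_a, " --(", mark, ")-- ", x$edges$gene_b,
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @noRd
edge_states <- function(g) {
  if (!nrow(g$edges)) return(stats::setNames(character(), character()))
  stats::setNames(g$edges$sign, paste(g$edges$gene_a, g$edges$gene_b, sep = "\r"))
}

#' Integer distance between two signed graphs
#'
#' Sums a per-gene-pair contribution over all pairs in the union vertex set:
#' 0 when the pair has the same state in both graphs, 1 when the edge exists
#' in exactly one graph, and 2 when it exists in both with a different
#' linking way (opposite sign). A pair involving a vertex absent from one
#' graph counts as edge-absent there. The per-pair contribution is a metric
#' on the three states, so the sum is a metric on signed graphs over a fixed
#' vertex set.
#'
#' @param g1,g2 `coreg_graph` objects.
#' @return Non-negative integer.
#' @export
graph_distance <- function(g1, g2) {
  graph_distance_report(g1, g2)$distance
}

#' Distance between two signed graphs, with per-pair contributions
#'
#' @param g1,g2 `coreg_graph` objects.
#' @return List with `distance`, `n_pairs_compared` (all unordered pairs of
#'   the union vertex set) and a `contributions` data frame listing the gene
#'   pairs that contribute, their state in each graph and their term.
#' @export
graph_distance_report <- function(g1, g2) {
  stopifnot(inherits(g1, "coreg_graph"), inherits(g2, "coreg_graph"))
  s1 <- edge_states(g1)
  s2 <- edge_states(g2)
  keys <- union(names(s1), names(s2))
  nv <- length(union(g1$vertices, g2$vertices))
  if (!length(keys)) {
    return(list(distance = 0L, n_pairs_compared = choose(nv, 2),
                contributions = data.frame(gene_a = character(),
                                           gene_b = character(),
                                           state_1 = character(),
                                           state_2 = character(),
                                           contribution = integer(),
                                           stringsAsFactors = FALSE)))
  }
  a1 <- ifelse(is.na(s1[keys]), "absent", s1[keys])
  a2 <- ifelse(is.na(s2[keys]), "absent", s2[keys])
  contrib <- ifelse(a1 == a2, 0L, ifelse(a1 == "absent" | a2 == "absent", 1L, 2L))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  df <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                   state_1 = unname(a1), state_2 = unname(a2),
                   contribution = unname(contrib), stringsAsFactors = FALSE)
  df <- df[df$contribution > 0, , drop = FALSE]
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  list(distance = as.integer(sum(contrib)), n_pairs_compared = choose(nv, 2),
       contributions = df)
}

#' Convert a co-regulation graph to an igraph object
#'
#' @param g A `coreg_graph`.
#' @return An undirected [igraph::graph] with vertex attribute `name` and
#'   edge attribute `sign`.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "coreg_graph"))
  ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ig <- igraph::add_vertices(ig, length(g$vertices), name = g$vertices)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, rbind(g$edges$gene_a, g$edges$gene_b),
                            sign = g$edges$sign)
  }
  ig
}

#' Write a co-regulation graph to file
#'
#' Supported formats: `"json"` (explicit vertex and edge lists; exact round
#' trip through [read_coreg_graph_json]), `"graphml"` (edge attribute
#' `sign`), and `"dot"` (positive edges blue, negative edges red, matching
#' the usual rendering of signed co-expression graphs).
#'
#' @param g A `coreg_graph`.
#' @param path Output path.
#' @param format One of `"json"`, `"graphml"`, `"dot"`.
#' @export
write_coreg_graph <- function(g, path, format = c("json", "graphml", "dot")) {
  stopifnot(inherits(g, "coreg_graph"))
  if (!is.character(format) || !format[1] %in% c("json", "graphml", "dot"))
    stop_validation(sprintf(
      "unknown graph format '%s'; supported formats: json, graphml, dot",
      format[1]))
  format <- format[1]
  if (format == "json") {
    payload <- list(vertices = g$vertices, edges = g$edges)
    json <- jsonlite::toJSON(payload, dataframe = "rows", digits = NA,
                             pretty = TRUE)
    writeLines(json, path)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  } else {
    col <- c(positive = "blue", negative = "red")
    lines <- c("graph coregulation {",
               paste0("  \"", g$vertices, "\";"))
    if (nrow(g$edges)) {
      lines <- c(lines,
                 paste0("  \"", g$edges$gene_a, "\" -- \"", g$edges$gene_b,
                        "\" [color=", col[g$edges$sign], "];"))
    }
    writeLines(c(lines, "}"), path)
  }
  invisible(path)
}

#' Read a co-regulation graph from its JSON serialization
#'
#' @param path Path to a file written by [write_coreg_graph] with
#'   `format = "json"`.
#' @return A `coreg_graph` equal to the one written.
#' @export
read_coreg_graph_json <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  edges <- payload$edges
  if (is.null(edges) || NROW(edges) == 0) edges <- NULL
  coreg_graph(unlist(payload$vertices), edges)
}
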