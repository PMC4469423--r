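#' Expression matrix container
#'
#' A validated samples-by-genes table of relative expression values on the
#' qPCR delta-Ct scale (typically 0-20; a value of 0 is read as "not
#' detected"). Rows are samples, columns genes.
#'
#' @param values Numeric matrix, samples in rows, genes in columns.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row. Defaults to the rownames of `values`.
#' @param gene_names Character vector of unique gene names, one per column.
#'   Defaults to the colnames of `values`.
#' @param allow_negative Accept negative values (off by default: delta-Ct
#'   derived relative expression is non-negative).
#' @return An object of class `expression_matrix`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("s", 1:3), c("A", "B")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_names = colnames(values),
                              allow_negative = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(gene_names))
    stop_validation("sample_ids and gene_names are required (or set dimnames)")
  sample_ids <- as.character(sample_ids)
  gene_names <- as.character(gene_names)
  if (nrow(values) != length(sample_ids))
    stop_validation(sprintf("row count (%d) != number of sample ids (%d)",
                            nrow(values), length(sample_ids)))
  if (ncol(values) != length(gene_names))
    stop_validation(sprintf("column count (%d) != number of gene names (%d)",
                            ncol(values), length(gene_names)))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop_validation(paste0("duplicated sample id(s): ",
                           paste(dup, collapse = ", ")))
  dup <- unique(gene_names[duplicated(gene_names)])
  if (length(dup))
    stop_validation(paste0("duplicated gene name(s): ",
                           paste(dup, collapse = ", ")))
  if (any(!is.finite(values)))
    stop_validation("all expression values must be finite (no NA/NaN/Inf)")
  if (!allow_negative && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop_validation(sprintf(
      "negative value at sample '%s', gene '%s' (use allow_negative = TRUE to permit)",
      sample_ids[bad[1]], gene_names[bad[2]]))
  }
  dimnames(values) <- list(sample_ids, gene_names)
  structure(list(values = values, sample_ids = sample_ids,
                 gene_names = gene_names),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  cat("  genes:", paste(x$gene_names, collapse = ", "), "\n")
  cat(sprintf("  value range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Row subset preserving validity.
#' @noRd
em_subset <- function(em, idx) {
  expression_matrix(em$values[idx, , drop = FALSE],
                    em$sample_ids[idx], em$gene_names,
                    allow_negative = TRUE)
}

#' @noRd
guess_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression table
#'
#' Reads a delimited text table with a header row; the first column holds
#' sample identifiers and the remaining columns one gene each. Cells must be
#' numeric and non-empty; duplicated sample ids or gene names, non-numeric
#' cells and (by default) negative values are hard errors that name the
#' offending entry.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param sep Field separator; `NULL` picks `","` for `.csv` and tab
#'   otherwise.
#' @param transpose Set if the file stores genes as rows and samples as
#'   columns; the table is transposed to the canonical samples-by-genes
#'   orientation after reading.
#' @param allow_negative Accept negative expression values.
#' @return An [expression_matrix] with row and column order as in the file.
#' @export
read_expression_table <- function(path, sep = NULL, transpose = FALSE,
                                  allow_negative = FALSE) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  sep <- guess_sep(path, sep)
  raw <- read.table(path, sep = sep, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "", blank.lines.skip = TRUE)
  if (nrow(raw) < 2 || ncol(raw) < 2)
    stop_validation("table needs a header row, at least one sample and one gene")
  header <- as.character(raw[1, ])
  ids <- as.character(raw[-1, 1])
  cols <- header[-1]
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | !nzchar(trimws(body)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_validation(sprintf(
      "non-numeric or empty cell at row %d ('%s'), column %d ('%s'): '%s'",
      bad[1, 1], ids[bad[1, 1]], bad[1, 2], cols[bad[1, 2]],
      body[bad[1, 1], bad[1, 2]]))
  }
  if (transpose) {
    num <- t(num)
    tmp <- ids; ids <- cols; cols <- tmp
  }
  expression_matrix(num, sample_ids = ids, gene_names = cols,
                    allow_negative = allow_negative)
}

#' Write an expression table
#'
#' Inverse of [read_expression_table]: values are serialized with 12
#' significant digits, so a read-write round trip reproduces the matrix to
#' within 1e-9 on the delta-Ct scale (0-20).
#'
#' @param em An [expression_matrix].
#' @param path Output path.
#' @param sep Field separator; `NULL` picks by file extension.
#' @export
write_expression_table <- function(em, path, sep = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  sep <- guess_sep(path, sep)
  out <- data.frame(sample_id = em$sample_ids,
                    apply(em$values, 2, function(v) formatC(v, digits = 12, format = "g")),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("sample_id", em$gene_names)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Two-column delimited table (`sample_id`, `label`) assigning a categorical
#' label (for example an estrogen-receptor status such as `"ER+"`) to each
#' sample.
#'
#' @param path Path to the annotation file.
#' @param em Optional [expression_matrix]; when given, every annotated
#'   sample id must occur in it.
#' @param sep Field separator; `NULL` picks by file extension.
#' @return A data frame with character columns `sample_id` and `label`.
#' @export
read_sample_annotation <- function(path, em = NULL, sep = NULL) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  sep <- guess_sep(path, sep)
  ann <- read.table(path, sep = sep, header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(ann) < 2)
    stop_validation("annotation table needs columns sample_id and label")
  ann <- data.frame(sample_id = ann[[1]], label = ann[[2]],
                    stringsAsFactors = FALSE)
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup))
    stop_validation(paste0("duplicated sample id(s) in annotation: ",
                           paste(dup, collapse = ", ")))
  if (!is.null(em)) {
    miss <- setdiff(ann$sample_id, em$sample_ids)
    if (length(miss))
      stop_validation(paste0("annotated sample id(s) absent from expression matrix: ",
                             paste(miss, collapse = ", ")))
  }
  ann
}
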