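#' @noRd
stop_validation <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("coregscan_validation_error", "error", "condition"),
                 list(message = msg, call = call)))
}

#' @noRd
stop_degeneracy <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("coregscan_degeneracy_error", "error", "condition"),
                 list(message = msg, call = call)))
}

# Deterministic 32-bit seed for a gene pair, symmetric in the gene names so
# results do not depend on pair ordering. Polynomial string hash folded with
# the master seed, kept below 2^31.
#' @noRd
pair_seed <- function(master_seed, gene_a, gene_b) {
  m <- 2147480009  # prime < 2^31; arithmetic stays exact in doubles
  g <- sort(c(gene_a, gene_b))
  h <- 0
  for (ch in utf8ToInt(paste(g, collapse = "\r"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer((h + (master_seed %% m) + m) %% m)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
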