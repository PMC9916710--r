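#' Construct a weighted GRN
#'
#' A directed, signed, weighted gene regulatory network stored as a square
#' adjacency matrix. Element `(i, j)` is the weight of the directed edge
#' from gene `i` (regulator) to gene `j` (target). The diagonal is
#' structurally zero: self-regulation is outside the edge universe.
#'
#' @param weights Square numeric matrix of edge weights.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   the row names of `weights`).
#' @return An object of class `weighted_grn` with fields `weights` and
#'   `gene_ids`.
#' @export
weighted_grn <- function(weights, gene_ids = rownames(weights)) {
  if (!is.matrix(weights) || !is.numeric(weights) ||
      nrow(weights) != ncol(weights)) {
    stop_metasem("`weights` must be a square numeric matrix",
                 "metasem_arg_error")
  }
  if (any(!is.finite(weights))) {
    stop_metasem("GRN weights must be finite", "metasem_value_error")
  }
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(weights)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(weights) || anyDuplicated(gene_ids)) {
    stop_metasem("`gene_ids` must be unique and match the matrix dimension",
                 "metasem_arg_error")
  }
  diag(weights) <- 0
  dimnames(weights) <- list(gene_ids, gene_ids)
  structure(list(weights = weights, gene_ids = gene_ids),
            class = "weighted_grn")
}

#' @export
print.weighted_grn <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf("<weighted_grn> %d genes, %d nonzero edges\n",
              length(x$gene_ids), nz))
  invisible(x)
}

#' Zero the diagonal of a GRN matrix
#'
#' Idempotent guard applied after every update that touches the adjacency:
#' off-diagonal entries are untouched, the diagonal is set to zero.
#'
#' @param grn A [weighted_grn()] or a bare square matrix.
#' @return Same type as the input, with a zero diagonal.
#' @export
mask_diagonal <- function(grn) {
  if (inherits(grn, "weighted_grn")) {
    diag(grn$weights) <- 0
    grn
  } else {
    if (!is.matrix(grn) || nrow(grn) != ncol(grn)) {
      stop_metasem("`grn` must be square", "metasem_arg_error")
    }
    diag(grn) <- 0
    grn
  }
}

#' Write a GRN as a dense weight table
#'
#' @param grn A [weighted_grn()].
#' @param path Output path (TSV: first column gene ids, header of gene ids).
#' @return `path`, invisibly.
#' @export
write_grn <- function(grn, path) {
  stopifnot(inherits(grn, "weighted_grn"))
  df <- data.frame(gene = grn$gene_ids, grn$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a dense GRN weight table written by [write_grn()]
#'
#' @param path Path to the TSV.
#' @return A [weighted_grn()].
#' @export
read_grn <- function(path) {
  if (!file.exists(path)) {
    stop_metasem(sprintf("GRN file not found: %s", path), "metasem_io_error")
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  weighted_grn(m, gene_ids = ids)
}

#' Write a ranked edge list
#'
#' @param ranked A `ranked_edges` data frame from [rank_edges()].
#' @param path Output path (TSV with columns regulator, target, score).
#' @return `path`, invisibly.
#' @export
write_ranked_edges <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export a GRN to GraphML
#'
#' Writes the nonzero edges (optionally only the strongest `top`) for use in
#' network viewers. Requires the `igraph` package.
#'
#' @param grn A [weighted_grn()].
#' @param path Output path.
#' @param top Optional cap on the number of edges, by absolute weight.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(grn, path, top = NULL) {
  stopifnot(inherits(grn, "weighted_grn"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop_metasem("GraphML export requires the `igraph` package",
                 "metasem_io_error")
  }
  idx <- which(grn$weights != 0, arr.ind = TRUE)
  w <- grn$weights[idx]
  if (!is.null(top) && length(w) > top) {
    keep <- order(-abs(w))[seq_len(top)]
    idx <- idx[keep, , drop = FALSE]
    w <- w[keep]
  }
  el <- cbind(grn$gene_ids[idx[, 1L]], grn$gene_ids[idx[, 2L]])
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1L], to = el[, 2L], weight = w),
    directed = TRUE,
    vertices = data.frame(name = grn$gene_ids)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
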