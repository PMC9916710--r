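#' Preprocess an expression matrix for network inference
#'
#' Applies the standard single-cell filtering used before training: genes
#' expressed (strictly positive) in fewer than `min_cell_frac` of cells are
#' removed, values are log-transformed as `log(1 + x)`, and the `top_k` genes
#' by per-gene standard deviation of the log values are retained, ordered by
#' descending standard deviation (ties broken by input order). Cells listed
#' in `cell_blacklist` (e.g. annotated low-quality cells) are dropped first.
#'
#' The fraction threshold is strict: a gene expressed in exactly
#' `min_cell_frac` of cells is kept. Standard deviation uses the population
#' formula (divide by n).
#'
#' @param expr A raw [expression_matrix()] (`normalization == "raw"`).
#' @param min_cell_frac Minimum fraction of cells in which a gene must be
#'   expressed (default 0.10).
#' @param top_k Number of most variable genes to keep (default 1000; all
#'   surviving genes are kept when fewer remain).
#' @param log_normalize Apply `log(1 + x)` (default `TRUE`).
#' @param cell_blacklist Optional cell identifiers to exclude before
#'   filtering.
#' @return An [expression_matrix()] tagged `"lognorm"` (or `"raw"` when
#'   `log_normalize = FALSE`).
#' @export
#' @examples
#' m <- matrix(rpois(40, 3), 4, 10)
#' expr <- expression_matrix(m)
#' preprocess(expr, top_k = 2)
preprocess <- function(expr, min_cell_frac = 0.10, top_k = 1000,
                       log_normalize = TRUE, cell_blacklist = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$normalization != "raw") {
    stop_metasem("preprocess expects a raw expression matrix",
                 "metasem_arg_error")
  }
  check_number(min_cell_frac, "min_cell_frac", min = 0, max = 1)
  top_k <- check_count(top_k, "top_k")
  check_flag(log_normalize, "log_normalize")

  m <- expr$values
  if (!is.null(cell_blacklist)) {
    keep_cells <- !(expr$cell_ids %in% cell_blacklist)
    m <- m[, keep_cells, drop = FALSE]
    if (!ncol(m)) {
      stop_metasem("all cells excluded by the blacklist", "metasem_empty_result")
    }
  }

  frac <- rowMeans(m > 0)
  keep <- frac >= min_cell_frac   # "less than" is strict, so == threshold stays
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) {
    stop_metasem("no genes survive the expression-fraction filter",
                 "metasem_empty_result")
  }

  if (log_normalize) m <- log1p(m)

  sds <- row_sd_pop(m)
  ord <- order(-sds)              # stable: ties keep input order
  ord <- ord[seq_len(min(top_k, length(ord)))]
  m <- m[ord, , drop = FALSE]

  expression_matrix(m, normalization = if (log_normalize) "lognorm" else "raw")
}

#' Select genes by variability or at random
#'
#' Subsets an expression matrix to `k` genes, either the top-`k` by per-gene
#' (population) standard deviation or a uniform random sample without
#' replacement. Used to compare dispersion-driven against random gene panels.
#'
#' @param expr An [expression_matrix()].
#' @param k Number of genes to keep.
#' @param mode `"by_std"` (descending standard deviation, ties by input
#'   order) or `"random"`.
#' @param seed Integer seed used for `mode = "random"`.
#' @return An [expression_matrix()] with `k` genes.
#' @export
select_genes <- function(expr, k, mode = c("by_std", "random"), seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"))
  mode <- match.arg(mode)
  k <- check_count(k, "k")
  if (k > length(expr$gene_ids)) {
    stop_metasem(sprintf("k (%d) exceeds the number of genes (%d)",
                         k, length(expr$gene_ids)),
                 "metasem_arg_error")
  }
  idx <- switch(mode,
    by_std = order(-row_sd_pop(expr$values))[seq_len(k)],
    random = with_seed(seed, sample(length(expr$gene_ids), k))
  )
  expression_matrix(expr$values[idx, , drop = FALSE],
                    normalization = expr$normalization)
}

#' Split cells into training batches
#'
#' Partitions the cells of an expression matrix into consecutive batches of
#' at most `batch_size` cells; the final partial batch is kept. Each epoch
#' sees every cell exactly once.
#'
#' @param expr An [expression_matrix()].
#' @param batch_size Cells per batch (default 64).
#' @param shuffle Randomize cell order before batching.
#' @param seed Seed used when `shuffle = TRUE`.
#' @return A list of batches, each a list with `values` (genes x cells
#'   matrix) and `cell_indices` (1-based column indices into `expr`).
#' @export
batch_iterator <- function(expr, batch_size = 64, shuffle = FALSE, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"))
  batch_size <- check_count(batch_size, "batch_size")
  check_flag(shuffle, "shuffle")
  n <- length(expr$cell_ids)
  ord <- if (shuffle) with_seed(seed, sample(n)) else seq_len(n)
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) {
    idx <- ord[s:min(s + batch_size - 1L, n)]
    list(values = expr$values[, idx, drop = FALSE], cell_indices = idx)
  })
}
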