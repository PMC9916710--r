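#' Construct an expression matrix
#'
#' A light container for a genes-by-cells numeric matrix together with gene
#' and cell identifiers and a normalization tag. All training and evaluation
#' functions in the package take and return this class.
#'
#' @param values Numeric matrix, genes in rows, cells in columns.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   the row names of `values`).
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   the column names of `values`).
#' @param normalization Either `"raw"` (non-negative counts or count-like
#'   values) or `"lognorm"` (log-scale values, ready for training).
#'
#' @return An object of class `expression_matrix`: a list with fields
#'   `values`, `gene_ids`, `cell_ids`, `normalization`.
#' @export
#' @examples
#' m <- matrix(rpois(6, 5), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' expr <- expression_matrix(m)
#' dim(expr$values)
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              normalization = c("raw", "lognorm")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_metasem("`values` must be a numeric matrix", "metasem_arg_error")
  }
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    stop_metasem("identifier lengths must match matrix dimensions",
                 "metasem_arg_error")
  }
  if (anyDuplicated(gene_ids)) {
    stop_metasem(sprintf("duplicate gene identifiers: %s",
                         paste(unique(gene_ids[duplicated(gene_ids)]),
                               collapse = ", ")),
                 "metasem_identifier_conflict")
  }
  if (anyDuplicated(cell_ids)) {
    stop_metasem(sprintf("duplicate cell identifiers: %s",
                         paste(unique(cell_ids[duplicated(cell_ids)]),
                               collapse = ", ")),
                 "metasem_identifier_conflict")
  }
  if (any(!is.finite(values))) {
    stop_metasem("expression values must be finite (no NA/NaN/Inf)",
                 "metasem_value_error")
  }
  if (normalization == "raw" && any(values < 0)) {
    stop_metasem("raw expression values must be non-negative",
                 "metasem_value_error")
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 normalization = normalization),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells (%s)\n",
              length(x$gene_ids), length(x$cell_ids), x$normalization))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from delimited text
#'
#' Expects a header row of cell identifiers and a first column of gene
#' identifiers (genes x cells). Files stored cells x genes are handled with
#' `genes_in_rows = FALSE`; the result is always genes x cells.
#'
#' @param path Path to a CSV/TSV file.
#' @param delimiter Field separator; guessed from the file extension when
#'   `NULL` (`.csv` gives `","`, anything else tab).
#' @param genes_in_rows `TRUE` when rows are genes (the native layout).
#' @param normalization Normalization tag to attach, `"raw"` by default.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = NULL, genes_in_rows = TRUE,
                            normalization = "raw") {
  check_flag(genes_in_rows, "genes_in_rows")
  if (!file.exists(path)) {
    stop_metasem(sprintf("expression file not found: %s", path),
                 "metasem_io_error")
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))
    stop_metasem(sprintf("non-numeric expression values in column(s): %s",
                         paste(names(df[-1L])[bad], collapse = ", ")),
                 "metasem_parse_error")
  }
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  expression_matrix(m, normalization = normalization)
}

#' Write an expression matrix to delimited text
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delimiter = "\t") {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene = expr$gene_ids, expr$values, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a ground-truth network
#'
#' @param edges Two-column data frame (regulator, target) of directed edges.
#' @param tf_ids Optional character vector of candidate regulators; when
#'   given, every edge regulator must belong to it.
#' @return An object of class `grn_truth` with fields `edges` (data frame
#'   with columns `regulator`, `target`) and `tf_ids` (or `NULL`).
#' @export
grn_truth <- function(edges, tf_ids = NULL) {
  edges <- data.frame(regulator = as.character(edges[[1L]]),
                      target = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  if (any(!nzchar(edges$regulator)) || any(!nzchar(edges$target))) {
    stop_metasem("edge identifiers must be non-empty strings",
                 "metasem_value_error")
  }
  self <- edges$regulator == edges$target
  if (any(self)) {
    warning(sprintf("dropping %d self-edge(s)", sum(self)))
    edges <- edges[!self, , drop = FALSE]
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  if (!is.null(tf_ids)) {
    tf_ids <- as.character(tf_ids)
    missing_tf <- setdiff(edges$regulator, tf_ids)
    if (length(missing_tf)) {
      stop_metasem(sprintf("edge regulators not in tf_ids: %s",
                           paste(missing_tf, collapse = ", ")),
                   "metasem_value_error")
    }
  }
  structure(list(edges = edges, tf_ids = tf_ids), class = "grn_truth")
}

#' @export
print.grn_truth <- function(x, ...) {
  cat(sprintf("<grn_truth> %d directed edges%s\n", nrow(x$edges),
              if (is.null(x$tf_ids)) ""
              else sprintf(", %d candidate regulators", length(x$tf_ids))))
  invisible(x)
}

#' Read a ground-truth edge list
#'
#' Two-column delimited text in the BEELINE refNetwork convention
#' (regulator, target). A header line is detected and skipped when its first
#' field matches common header labels. Self-edges are dropped with a warning
#' and duplicate edges are de-duplicated.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field separator; guessed from the extension when `NULL`.
#' @param tf_ids Optional candidate-regulator identifiers.
#' @return A [grn_truth()].
#' @export
read_network <- function(path, delimiter = NULL, tf_ids = NULL) {
  if (!file.exists(path)) {
    stop_metasem(sprintf("network file not found: %s", path),
                 "metasem_io_error")
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    stop_metasem("network file is empty", "metasem_parse_error")
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop_metasem(sprintf("malformed network row at line %d: expected 2 fields, got %d",
                         bad[1L], length(fields[[bad[1L]]])),
                 "metasem_parse_error")
  }
  first <- tolower(trimws(fields[[1L]]))
  header_words <- c("gene1", "regulator", "tf", "source", "from")
  if (first[1L] %in% header_words) fields <- fields[-1L]
  reg <- trimws(vapply(fields, `[[`, character(1), 1L))
  tgt <- trimws(vapply(fields, `[[`, character(1), 2L))
  grn_truth(data.frame(regulator = reg, target = tgt,
                       stringsAsFactors = FALSE), tf_ids = tf_ids)
}

#' Read a candidate-regulator (TF) list
#'
#' Plain text, one identifier per line; blank lines ignored.
#'
#' @param path Path to the list.
#' @return Character vector of identifiers.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) {
    stop_metasem(sprintf("TF list not found: %s", path), "metasem_io_error")
  }
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) ids <- unique(ids)
  ids
}

#' Write a ground-truth edge list
#'
#' @param truth A [grn_truth()].
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_network <- function(truth, path, delimiter = "\t") {
  stopifnot(inherits(truth, "grn_truth"))
  utils::write.table(truth$edges, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
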