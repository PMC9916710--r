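#' Rank candidate edges of a GRN
#'
#' Scores every ordered non-self gene pair by the absolute SEM weight (or by
#' the signed weight with `signed = TRUE`) and returns them in descending
#' score order. Ties are broken deterministically by (regulator, target)
#' lexicographic order. When a candidate-regulator list is given, the
#' candidate universe is restricted to pairs whose regulator belongs to it.
#'
#' @param grn A [weighted_grn()].
#' @param tf_ids Optional candidate-regulator identifiers.
#' @param signed Rank by signed weight instead of absolute value.
#' @return A data frame of class `ranked_edges` with columns `regulator`,
#'   `target`, `score`, descending.
#' @export
rank_edges <- function(grn, tf_ids = NULL, signed = FALSE) {
  stopifnot(inherits(grn, "weighted_grn"))
  check_flag(signed, "signed")
  ids <- grn$gene_ids
  regs <- ids
  if (!is.null(tf_ids)) {
    regs <- intersect(ids, as.character(tf_ids))
    if (!length(regs)) {
      stop_metasem("no candidate regulators present among the GRN genes",
                   "metasem_empty_universe")
    }
  }
  reg <- rep(regs, each = length(ids))
  tgt <- rep(ids, times = length(regs))
  keep <- reg != tgt
  reg <- reg[keep]; tgt <- tgt[keep]
  w <- grn$weights[cbind(match(reg, ids), match(tgt, ids))]
  score <- if (signed) w else abs(w)
  ord <- order(-score, reg, tgt, method = "radix")
  structure(data.frame(regulator = reg[ord], target = tgt[ord],
                       score = score[ord], stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("ranked_edges", "data.frame"))
}

# Binary labels of the ranked candidates against a truth network; truth
# edges outside the candidate universe are dropped with a warning.
edge_labels <- function(ranked, truth) {
  stopifnot(inherits(truth, "grn_truth"))
  cand_key <- paste(ranked$regulator, ranked$target, sep = "\r")
  truth_key <- paste(truth$edges$regulator, truth$edges$target, sep = "\r")
  outside <- !(truth_key %in% cand_key)
  if (any(outside)) {
    warning(sprintf("%d ground-truth edge(s) outside the candidate universe were dropped",
                    sum(outside)))
    truth_key <- truth_key[!outside]
  }
  if (!length(truth_key)) {
    stop_metasem("no ground-truth edges fall inside the candidate universe",
                 "metasem_undefined_metric")
  }
  cand_key %in% truth_key
}

#' Early precision ratio
#'
#' Precision among the top-K ranked edges, with K equal to the number of
#' ground-truth edges, divided by the precision expected from a random
#' predictor (the density of true edges in the candidate universe). A value
#' of 1 means no better than random.
#'
#' @param ranked A [rank_edges()] result.
#' @param truth A [grn_truth()].
#' @return The EPR (non-negative scalar).
#' @export
early_precision_ratio <- function(ranked, truth) {
  lab <- edge_labels(ranked, truth)
  k <- sum(lab)
  n <- length(lab)
  precision_k <- mean(lab[seq_len(k)])
  density <- k / n
  precision_k / density
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over the ranked candidate list: AUPR =
#' sum over recall increments of the precision at each newly recovered true
#' edge (average-precision form).
#'
#' @inheritParams early_precision_ratio
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(ranked, truth) {
  lab <- edge_labels(ranked, truth)
  npos <- sum(lab)
  if (npos == length(lab)) {
    stop_metasem("every candidate is a true edge; AUPR is undefined",
                 "metasem_undefined_metric")
  }
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  sum(precision[lab]) / npos
}

#' Area under the ROC curve
#'
#' Computed from the rank statistic (Mann-Whitney form) on the scores, with
#' tied scores receiving their average rank — equivalent to the trapezoidal
#' area under the ROC curve.
#'
#' @inheritParams early_precision_ratio
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(ranked, truth) {
  lab <- edge_labels(ranked, truth)
  npos <- sum(lab)
  nneg <- length(lab) - npos
  if (nneg == 0L) {
    stop_metasem("every candidate is a true edge; AUROC is undefined",
                 "metasem_undefined_metric")
  }
  r <- rank(ranked$score)
  (sum(r[lab]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate a GRN against a ground-truth network
#'
#' Convenience wrapper computing EPR, AUPR and AUROC in one pass.
#'
#' @param grn A [weighted_grn()].
#' @param truth A [grn_truth()].
#' @param tf_ids Optional candidate-regulator restriction; defaults to the
#'   truth's `tf_ids` when present.
#' @return A list of class `eval_result`: `epr`, `aupr`, `auroc`, `k`,
#'   `n_candidates`, `n_positives`, and the `ranked` edge list.
#' @export
evaluate_grn <- function(grn, truth, tf_ids = truth$tf_ids) {
  ranked <- rank_edges(grn, tf_ids = tf_ids)
  lab <- edge_labels(ranked, truth)
  res <- list(
    epr = early_precision_ratio(ranked, truth),
    aupr = aupr(ranked, truth),
    auroc = auroc(ranked, truth),
    k = sum(lab),
    n_candidates = length(lab),
    n_positives = sum(lab),
    ranked = ranked
  )
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> EPR %.3f | AUPR %.3f | AUROC %.3f (K = %d of %d candidates)\n",
              x$epr, x$aupr, x$auroc, x$k, x$n_candidates))
  invisible(x)
}

#' Aggregate regulatory weight per gene
#'
#' The regulatory weight of a gene is the sum of the absolute weights of its
#' outgoing edges — how strongly it acts as a regulator in the inferred SEM.
#'
#' @param grn A [weighted_grn()].
#' @return A data frame (`gene`, `weight`) sorted by descending weight.
#' @export
regulator_weights <- function(grn) {
  stopifnot(inherits(grn, "weighted_grn"))
  w <- rowSums(abs(grn$weights))
  ord <- order(-w, grn$gene_ids, method = "radix")
  data.frame(gene = grn$gene_ids[ord], weight = unname(w[ord]),
             stringsAsFactors = FALSE)
}

#' Pearson correlation between two GRNs
#'
#' Aligns the two networks on their shared genes, flattens the off-diagonal
#' entries of both weight matrices in identical order, and returns the
#' Pearson correlation. The structurally zero diagonal is excluded so it
#' cannot inflate the correlation.
#'
#' @param a,b [weighted_grn()] objects.
#' @return A list `list(r, n_shared)`.
#' @export
grn_correlation <- function(a, b) {
  stopifnot(inherits(a, "weighted_grn"), inherits(b, "weighted_grn"))
  shared <- intersect(a$gene_ids, b$gene_ids)
  if (length(shared) < 2L) {
    stop_metasem("fewer than 2 shared genes between the networks",
                 "metasem_arg_error")
  }
  wa <- a$weights[shared, shared]
  wb <- b$weights[shared, shared]
  off <- row(wa) != col(wa)
  va <- wa[off]; vb <- wb[off]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop_metasem("zero variance in off-diagonal weights; correlation undefined",
                 "metasem_undefined_correlation")
  }
  list(r = stats::cor(va, vb), n_shared = length(shared))
}
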