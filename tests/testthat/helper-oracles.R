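# Independent brute-force oracles for the edge-ranking metrics, plus small
# fixture builders. The oracles deliberately share no code with the package:
# AUROC by exhaustive pairwise comparison, AUPR by walking the full PR
# curve, EPR by enumerating the candidate universe directly.

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision: walk the ranked labels, summing precision at each hit.
oracle_aupr <- function(labels_in_rank_order) {
  tp <- 0
  ap <- 0
  for (i in seq_along(labels_in_rank_order)) {
    if (labels_in_rank_order[i]) {
      tp <- tp + 1
      ap <- ap + tp / i
    }
  }
  ap / sum(labels_in_rank_order)
}

# EPR from scratch: enumerate every ordered non-self pair, sort by absolute
# weight (ties lexicographic), take the top K = |truth|.
oracle_epr <- function(grn, truth_edges) {
  ids <- grn$gene_ids
  cand <- expand.grid(regulator = ids, target = ids,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$regulator != cand$target, ]
  cand$score <- abs(grn$weights[cbind(match(cand$regulator, ids),
                                      match(cand$target, ids))])
  cand <- cand[order(-cand$score, cand$regulator, cand$target), ]
  key <- paste(cand$regulator, cand$target)
  truth_key <- paste(truth_edges$regulator, truth_edges$target)
  k <- length(truth_key)
  precision <- mean(key[seq_len(k)] %in% truth_key)
  precision / (k / nrow(cand))
}

# Truth membership of ranked candidates, independent of the package's
# internal labelling.
edge_is_true <- function(ranked, truth) {
  paste(ranked$regulator, ranked$target) %in%
    paste(truth$edges$regulator, truth$edges$target)
}

# Random weighted GRN with continuous (almost surely untied) scores.
random_grn <- function(G, seed) {
  withr::with_seed(seed, {
    w <- matrix(rnorm(G * G), G, G)
    weighted_grn(w, gene_ids = sprintf("g%02d", seq_len(G)))
  })
}

# Random truth with n_edges edges among the ordered non-self pairs.
random_truth <- function(G, n_edges, seed) {
  ids <- sprintf("g%02d", seq_len(G))
  pairs <- expand.grid(regulator = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  withr::with_seed(seed, {
    grn_truth(pairs[sample(nrow(pairs), n_edges), ])
  })
}

# The hand-checkable 4 genes x 10 cells preprocessing fixture:
#   g_zero: all zeros                      -> removed (fraction 0 < 0.10)
#   g_rare: nonzero in exactly 1/10 cells  -> kept (fraction 0.10, not <)
#   g_const: constant 5                    -> kept, log-sd 0 (ranks last)
#   g_var: variable                        -> kept, highest log-sd
toy_preprocess_matrix <- function() {
  m <- rbind(
    g_zero  = rep(0, 10),
    g_rare  = c(7, rep(0, 9)),
    g_const = rep(5, 10),
    g_var   = c(0, 1, 2, 4, 8, 16, 2, 1, 9, 3)
  )
  colnames(m) <- paste0("c", 1:10)
  expression_matrix(m)
}

# Small trained-free model fixture for shape/arithmetic tests.
tiny_model <- function(G = 3, hidden_dim = 4, seed = 11,
                       activation = "relu") {
  init_model(G, hidden_dim = hidden_dim, seed = seed,
             activation = activation)
}
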