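#' Simulation configuration for the linear-SEM generator
#'
#' Defines the ground-truth network and expression model used to generate
#' benchmark data: a sparse directed weighted adjacency `A` over `n_genes`
#' genes and expression drawn from the linear structural equation model
#' `X = t(A) X + E`, i.e. `X = solve(I - t(A)) E` with i.i.d. Gaussian
#' noise `E`. Optional dropout zeroes entries independently to mimic
#' scRNA-seq sparsity.
#'
#' Defaults describe the benchmark condition used throughout the package's
#' own validation: 20 genes, 1000 cells, 10% of ordered gene pairs carrying
#' an edge, absolute weights in (0.5, 1.5) with 30% negative, unit noise,
#' no dropout, acyclic graph.
#'
#' @param n_genes Number of genes.
#' @param n_cells Number of cells.
#' @param edge_density Expected fraction of ordered non-self gene pairs that
#'   carry an edge, in (0, 1).
#' @param weight_low,weight_high Bounds of the absolute edge-weight range.
#' @param sign_mix Fraction of edges with negative sign, in `[0, 1]`.
#' @param noise_sd Standard deviation of the SEM noise (> 0).
#' @param dropout_rate Independent per-entry zeroing probability, in `[0, 1)`.
#' @param seed Integer seed; the adjacency and the expression draw are both
#'   reproducible from it.
#' @param graph_mode `"dag"` (acyclic by construction: edges respect a random
#'   gene ordering) or `"stable"` (cycles allowed; the matrix is rescaled so
#'   its spectral radius stays below 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20, n_cells = 1000, edge_density = 0.1,
                       weight_low = 0.5, weight_high = 1.5, sign_mix = 0.3,
                       noise_sd = 1, dropout_rate = 0, seed = 1L,
                       graph_mode = c("dag", "stable")) {
  graph_mode <- match.arg(graph_mode)
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 2L),
    n_cells = check_count(n_cells, "n_cells", min = 1L),
    edge_density = check_number(edge_density, "edge_density",
                                min = 0, max = 1, strict_min = TRUE,
                                strict_max = TRUE),
    weight_low = check_number(weight_low, "weight_low", min = 0),
    weight_high = check_number(weight_high, "weight_high", min = 0),
    sign_mix = check_number(sign_mix, "sign_mix", min = 0, max = 1),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE),
    dropout_rate = check_number(dropout_rate, "dropout_rate", min = 0,
                                max = 1, strict_max = TRUE),
    seed = check_count(seed, "seed", min = 0L),
    graph_mode = graph_mode
  )
  if (cfg$weight_low > cfg$weight_high) {
    stop_metasem("weight_low must not exceed weight_high", "metasem_arg_error")
  }
  if (graph_mode == "dag" && 2 * cfg$edge_density > 1) {
    stop_metasem("dag mode supports edge_density <= 0.5 (admissible pairs are half the ordered pairs)",
                 "metasem_sim_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a ground-truth adjacency matrix
#'
#' Draws a sparse signed weighted adjacency with zero diagonal. In `"dag"`
#' mode a random gene ordering is drawn and each ordered pair respecting it
#' receives an edge with probability `2 * edge_density`, so the expected
#' fraction of all ordered non-self pairs carrying an edge equals
#' `edge_density` and the graph is acyclic by construction. In `"stable"`
#' mode every ordered pair is eligible with probability `edge_density` and
#' the matrix is rescaled to spectral radius 0.95 if it reaches 1 or above,
#' keeping `I - t(A)` well conditioned.
#'
#' @param cfg A [sim_config()].
#' @return A [weighted_grn()]; the true network.
#' @export
make_adjacency <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  G <- cfg$n_genes
  A <- with_seed(cfg$seed, {
    A <- matrix(0, G, G)
    off <- which(row(A) != col(A))
    if (cfg$graph_mode == "dag") {
      perm <- sample(G)
      admissible <- off[perm[row(A)[off]] < perm[col(A)[off]]]
      p_edge <- 2 * cfg$edge_density
    } else {
      admissible <- off
      p_edge <- cfg$edge_density
    }
    hit <- admissible[stats::runif(length(admissible)) < p_edge]
    w <- stats::runif(length(hit), cfg$weight_low, cfg$weight_high)
    neg <- stats::runif(length(hit)) < cfg$sign_mix
    w[neg] <- -w[neg]
    A[hit] <- w
    A
  })
  if (cfg$graph_mode == "stable") {
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rho >= 1) {
      A <- A * (0.95 / rho)
      rho2 <- max(Mod(eigen(A, only.values = TRUE)$values))
      if (rho2 >= 1) {
        stop_metasem("could not rescale adjacency to spectral radius < 1",
                     "metasem_sim_config_error")
      }
    }
  }
  weighted_grn(A, gene_ids = paste0("g", seq_len(G)))
}

#' Simulate expression from a linear SEM
#'
#' Draws `E ~ Normal(0, noise_sd^2)` i.i.d. and solves
#' `X = solve(I - t(A)) E`, genes x cells. With `dropout_rate > 0` the
#' matrix is shifted so its minimum is zero (raw-like non-negative values)
#' and entries are then zeroed independently with probability
#' `dropout_rate`; the result is tagged `"raw"`. Without dropout the
#' continuous log-scale-like values are returned unchanged, tagged
#' `"lognorm"` so they feed training directly.
#'
#' @param A A [weighted_grn()], typically from [make_adjacency()].
#' @param cfg The [sim_config()] (uses `n_cells`, `noise_sd`,
#'   `dropout_rate`, `seed`).
#' @param return_noise Also return the noise matrix `E`.
#' @return An [expression_matrix()]; with `return_noise = TRUE`, a list
#'   `list(expr, noise)`.
#' @export
simulate_expression <- function(A, cfg, return_noise = FALSE) {
  stopifnot(inherits(A, "weighted_grn"), inherits(cfg, "sim_config"))
  G <- length(A$gene_ids)
  n <- cfg$n_cells
  IA <- diag(G) - t(A$weights)
  det_ok <- abs(det(IA)) > .Machine$double.eps * G
  if (!det_ok) {
    stop_metasem("I - t(A) is singular; use graph_mode 'dag' or 'stable'",
                 "metasem_sim_error")
  }
  out <- with_seed(cfg$seed + 1L, {
    E <- matrix(stats::rnorm(G * n, 0, cfg$noise_sd), G, n)
    X <- solve(IA, E)
    if (cfg$dropout_rate > 0) {
      X <- X - min(X)  # shift to raw-like non-negative values
      keep <- matrix(stats::runif(G * n) >= cfg$dropout_rate, G, n)
      X <- X * keep
    }
    list(X = X, E = E)
  })
  dimnames(out$X) <- list(A$gene_ids, paste0("c", seq_len(n)))
  expr <- expression_matrix(out$X,
                            normalization = if (cfg$dropout_rate > 0) "raw"
                                            else "lognorm")
  if (return_noise) list(expr = expr, noise = out$E) else expr
}

#' Convert a ground-truth adjacency into an edge list
#'
#' @param A A [weighted_grn()].
#' @return A [grn_truth()] holding the nonzero directed edges.
#' @export
adjacency_to_truth <- function(A) {
  stopifnot(inherits(A, "weighted_grn"))
  idx <- which(A$weights != 0, arr.ind = TRUE)
  if (!nrow(idx)) {
    stop_metasem("adjacency has no edges", "metasem_empty_result")
  }
  grn_truth(data.frame(regulator = A$gene_ids[idx[, 1L]],
                       target = A$gene_ids[idx[, 2L]],
                       stringsAsFactors = FALSE))
}
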