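# Model core: encoder, meta-decoder, and the embedded SEM adjacency.
#
# Both networks are multilayer perceptrons applied gene-wise with weights
# shared across genes (1x1-convolution style): each expression value passes
# through a scalar-in/scalar-out channel MLP with `hidden_dim` hidden
# neurons. Sharing weights across genes preserves gene identity in the
# feature map, which is what makes the SEM adjacency identifiable: the only
# way information can move between genes is through t(A), and the zero
# diagonal forces each gene's pseudo-label to be predicted from *other*
# genes. The encoder is a three-layer MLP (1 -> H -> H -> 1 per value), the
# meta-decoder a two-layer MLP (1 -> H -> 1 per value) applied after t(A).

act_fun <- function(x, activation) {
  if (activation == "relu") pmax(x, 0) else x
}
act_grad <- function(pre, activation) {
  if (activation == "relu") (pre > 0) * 1 else 1
}

glorot_uniform <- function(n, fan_in, fan_out) {
  stats::runif(n, -1, 1) * sqrt(6 / (fan_in + fan_out))
}

#' Initialize model parameters and the SEM adjacency
#'
#' Encoder and decoder weights are drawn from a scaled symmetric (Glorot)
#' uniform distribution with zero biases. The GRN layer starts as small
#' symmetric-random off-diagonal values, uniform on (-0.1, 0.1), with a zero
#' diagonal.
#'
#' @param G Number of genes (>= 2).
#' @param hidden_dim Hidden neurons per layer (default 128).
#' @param seed Integer seed; initialization is bit-reproducible under it.
#' @param activation `"relu"` (default) or `"linear"` (no nonlinearity;
#'   useful for analytic checks).
#' @param gene_ids Optional gene identifiers for the GRN.
#' @return A list with `params` (class `metasem_params`) and `grn`
#'   (a [weighted_grn()]).
#' @export
init_model <- function(G, hidden_dim = 128, seed = 1L, activation = c("relu", "linear"),
                       gene_ids = NULL) {
  activation <- match.arg(activation)
  G <- check_count(G, "G", min = 2L)
  H <- check_count(hidden_dim, "hidden_dim")
  out <- with_seed(seed, {
    params <- list(
      encoder = list(
        w1 = glorot_uniform(H, 1, H), b1 = numeric(H),
        W2 = matrix(glorot_uniform(H * H, H, H), H, H), b2 = numeric(H),
        w3 = glorot_uniform(H, H, 1), b3 = 0
      ),
      decoder = list(
        v1 = glorot_uniform(H, 1, H), c1 = numeric(H),
        v2 = glorot_uniform(H, H, 1), c2 = 0
      ),
      hidden_dim = H,
      activation = activation
    )
    A <- matrix(stats::runif(G * G, -0.1, 0.1), G, G)
    list(params = params, A = A)
  })
  class(out$params) <- "metasem_params"
  list(params = out$params,
       grn = weighted_grn(out$A, gene_ids = gene_ids))
}

#' @export
print.metasem_params <- function(x, ...) {
  cat(sprintf("<metasem_params> hidden_dim %d, activation %s\n",
              x$hidden_dim, x$activation))
  invisible(x)
}

# Full encoder forward pass with intermediates kept for backprop.
encoder_forward_full <- function(params, x) {
  enc <- params$encoder
  s <- as.vector(x)
  a1 <- outer(enc$w1, s) + enc$b1
  h1 <- act_fun(a1, params$activation)
  a2 <- enc$W2 %*% h1 + enc$b2
  h2 <- act_fun(a2, params$activation)
  e <- as.vector(crossprod(enc$w3, h2)) + enc$b3
  list(e = matrix(e, nrow(x), ncol(x)), a1 = a1, h1 = h1, a2 = a2, h2 = h2,
       s = s)
}

decoder_forward_full <- function(params, z) {
  dec <- params$decoder
  s <- as.vector(z)
  d1a <- outer(dec$v1, s) + dec$c1
  d1 <- act_fun(d1a, params$activation)
  y <- as.vector(crossprod(dec$v2, d1)) + dec$c2
  list(y = matrix(y, nrow(z), ncol(z)), d1a = d1a, d1 = d1, s = s)
}

#' Encoder forward pass
#'
#' Maps a genes-by-cells batch to feature vectors of the same shape: each
#' value passes through the shared three-layer channel MLP, so the gene
#' dimension is preserved and pseudo-labels can be compared elementwise.
#'
#' @param params A `metasem_params` object from [init_model()].
#' @param x Numeric genes-by-cells matrix (a batch).
#' @return Feature matrix of the same shape as `x`.
#' @export
encoder_forward <- function(params, x) {
  stopifnot(inherits(params, "metasem_params"))
  if (!is.matrix(x)) x <- as.matrix(x)
  encoder_forward_full(params, x)$e
}

#' Meta-decoder forward pass
#'
#' Produces pseudo-labels as literal SEM reconstructions: the features are
#' first mixed across genes by `t(A)` (each gene receives a weighted sum of
#' its candidate regulators' features; the zero diagonal excludes the gene
#' itself) and the result passes through the shared two-layer channel MLP.
#'
#' @param params A `metasem_params` object.
#' @param grn A [weighted_grn()] with one row/column per gene of `xp`.
#' @param xp Feature matrix (genes x cells), e.g. from [encoder_forward()].
#' @return Pseudo-label matrix of the same shape as `xp`.
#' @export
decoder_forward <- function(params, grn, xp) {
  stopifnot(inherits(params, "metasem_params"), inherits(grn, "weighted_grn"))
  if (!is.matrix(xp)) xp <- as.matrix(xp)
  if (nrow(xp) != length(grn$gene_ids)) {
    stop_metasem("feature rows must match the GRN dimension",
                 "metasem_arg_error")
  }
  z <- t(grn$weights) %*% xp
  decoder_forward_full(params, z)$y
}

#' Blend encoder features with a feature matrix
#'
#' `X^p* = 0.5 * encoder(x) + xp`. During training `xp` is the raw batch
#' (a residual anchor to the observed expression); the blend is the
#' pseudo-label target the decoder's SEM reconstruction is compared with.
#'
#' @param params A `metasem_params` object.
#' @param x Input batch (genes x cells).
#' @param xp Feature matrix of the same shape.
#' @return Blended matrix of the same shape.
#' @export
feature_blend <- function(params, x, xp) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.matrix(xp)) xp <- as.matrix(xp)
  if (!all(dim(x) == dim(xp))) {
    stop_metasem("`x` and `xp` must have identical shapes", "metasem_arg_error")
  }
  0.5 * encoder_forward(params, x) + xp
}

#' GRN-layer iteration
#'
#' Epoch-level refresh of the SEM adjacency: a convex blend of the matrix
#' after the current round of decoder-driven optimizer steps (`A_new`) with
#' the matrix the epoch started from (`A_prev`). The retention coefficient
#' `alpha` controls how fast the layer moves in the new iteration:
#' `A* = (1 - alpha) * A_new + alpha * A_prev`, diagonal re-zeroed.
#'
#' @param A_new,A_prev [weighted_grn()] objects with identical gene order.
#' @param alpha Retention coefficient in `[0, 1]` (default 0.1).
#' @return A [weighted_grn()].
#' @export
grn_layer_update <- function(A_new, A_prev, alpha = 0.1) {
  stopifnot(inherits(A_new, "weighted_grn"), inherits(A_prev, "weighted_grn"))
  check_number(alpha, "alpha", min = 0, max = 1)
  if (!identical(A_new$gene_ids, A_prev$gene_ids)) {
    stop_metasem("gene order differs between the two matrices",
                 "metasem_arg_error")
  }
  w <- (1 - alpha) * A_new$weights + alpha * A_prev$weights
  weighted_grn(w, gene_ids = A_new$gene_ids)
}

# ---- joint forward/backward pass -------------------------------------------
#
# Training objective on one batch:
#   target  t  = 0.5 * e_tgt + x             (treated as a constant target)
#   predict yp = decoder(t(A) %*% encoder(x))
#   loss       = fit(t, yp) + beta * sum(w1^2)
# The blend target is a pseudo-label and, as in standard self-training, is
# detached: no gradient flows through it. `tgt_e` supplies the encoder
# features used in the target; the training loop passes features computed
# once from the initial encoder and held fixed (anchored pseudo-labels),
# which keeps the objective stationary and the loss descending.
# When `tgt_e` is NULL the live encoder output is used (still detached).
# The encoder is trained through the decoder path, the decoder through its
# own layers, and A through t(A). fit is mean squared error by default;
# "bce" applies binary cross-entropy to min-max scaled values (scaling
# constants treated as fixed).

model_forward_backward <- function(params, grn, x, beta, loss_kind = "mse",
                                   tgt_e = NULL) {
  A <- grn$weights
  G <- nrow(x); B <- ncol(x); N <- G * B
  ef <- encoder_forward_full(params, x)
  e <- ef$e
  z <- t(A) %*% e
  df <- decoder_forward_full(params, z)
  yp <- df$y
  tgt <- 0.5 * (if (is.null(tgt_e)) e else tgt_e) + x

  if (loss_kind == "mse") {
    diff <- tgt - yp
    fit <- mean(diff^2)
    g_yp <- -2 * diff / N
  } else { # bce on min-max scaled values; scale constants detached
    lo <- min(tgt, yp); hi <- max(tgt, yp)
    span <- max(hi - lo, .Machine$double.eps)
    p <- pmin(pmax((yp - lo) / span, 1e-7), 1 - 1e-7)
    tt <- pmin(pmax((tgt - lo) / span, 1e-7), 1 - 1e-7)
    fit <- mean(-tt * log(p) - (1 - tt) * log(1 - p))
    g_yp <- (p - tt) / (p * (1 - p)) / N / span
  }
  enc <- params$encoder; dec <- params$decoder
  loss <- fit + beta * sum(enc$w1^2)
  if (!is.finite(loss)) {
    stop_metasem("non-finite training loss", "metasem_numerical_failure")
  }

  g_y <- as.vector(g_yp)
  dv2 <- as.vector(df$d1 %*% g_y); dc2 <- sum(g_y)
  g_d1 <- dec$v2 %o% g_y
  g_d1a <- g_d1 * act_grad(df$d1a, params$activation)
  dv1 <- as.vector(g_d1a %*% df$s); dc1 <- rowSums(g_d1a)
  g_z <- matrix(colSums(g_d1a * dec$v1), G, B)
  dA <- e %*% t(g_z)
  diag(dA) <- 0                    # diagonal is frozen at zero
  g_e <- A %*% g_z                 # encoder gradient via the decoder path only

  g_ev <- as.vector(g_e)
  dw3 <- as.vector(ef$h2 %*% g_ev); db3 <- sum(g_ev)
  g_h2 <- enc$w3 %o% g_ev
  g_a2 <- g_h2 * act_grad(ef$a2, params$activation)
  dW2 <- g_a2 %*% t(ef$h1); db2 <- rowSums(g_a2)
  g_h1 <- crossprod(enc$W2, g_a2)
  g_a1 <- g_h1 * act_grad(ef$a1, params$activation)
  dw1 <- as.vector(g_a1 %*% ef$s) + 2 * beta * enc$w1
  db1 <- rowSums(g_a1)

  list(
    loss = loss, fit = fit, reg = beta * sum(enc$w1^2),
    grads = list(
      encoder = list(w1 = dw1, b1 = db1, W2 = dW2, b2 = db2,
                     w3 = dw3, b3 = db3),
      decoder = list(v1 = dv1, c1 = dc1, v2 = dv2, c2 = dc2),
      A = dA
    )
  )
}
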