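#' Training configuration
#'
#' Collects the hyperparameters of the bi-level training loop. Defaults are
#' the standard settings used throughout the package: 128 hidden neurons,
#' batches of 64 cells, Adam with learning rate 1e-4 for the encoder and
#' 5e-4 for the meta-decoder (which also carries the SEM adjacency), a
#' one-step gradient probe with learning rate 1e-2, epoch-level GRN-layer
#' blending with retention `alpha = 0.1`, and an L2 penalty `beta = 1e-4`
#' on the encoder's first-layer weights.
#'
#' @param hidden_dim Hidden neurons per MLP layer.
#' @param batch_size Cells per batch.
#' @param lr_encoder,lr_decoder Adam learning rates for encoder and
#'   meta-decoder (the decoder group includes the adjacency).
#' @param lr_onestep Step size of the plain gradient-descent probe.
#' @param alpha GRN-layer retention coefficient in `[0, 1]`.
#' @param beta Weight of the L2 penalty on the encoder's first layer.
#' @param epochs Number of training epochs (>= 1).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param loss_kind `"mse"` (default) or `"bce"` (binary cross-entropy on
#'   min-max scaled values).
#' @param cv_folds 0 for no cross-validation (the default for network
#'   inference), or the number of folds for robustness experiments.
#' @param activation `"relu"` or `"linear"`.
#' @param probe_rule Probe acceptance rule: `"loss"` (accept when the probe
#'   loss drops) or `"grad_norm"` (accept when the gradient norm drops).
#' @param shuffle Shuffle cells into batches each epoch.
#' @return A list of class `train_config`.
#' @export
train_config <- function(hidden_dim = 128, batch_size = 64,
                         lr_encoder = 1e-4, lr_decoder = 5e-4,
                         lr_onestep = 1e-2, alpha = 0.1, beta = 1e-4,
                         epochs = 60, seed = 1L,
                         loss_kind = c("mse", "bce"), cv_folds = 0,
                         activation = c("relu", "linear"),
                         probe_rule = c("loss", "grad_norm"),
                         shuffle = TRUE) {
  cfg <- list(
    hidden_dim = check_count(hidden_dim, "hidden_dim"),
    batch_size = check_count(batch_size, "batch_size"),
    lr_encoder = check_number(lr_encoder, "lr_encoder", min = 0),
    lr_decoder = check_number(lr_decoder, "lr_decoder", min = 0),
    lr_onestep = check_number(lr_onestep, "lr_onestep", min = 0),
    alpha = check_number(alpha, "alpha", min = 0, max = 1),
    beta = check_number(beta, "beta", min = 0),
    epochs = check_count(epochs, "epochs"),
    seed = check_count(seed, "seed", min = 0L),
    loss_kind = match.arg(loss_kind),
    cv_folds = check_count(cv_folds, "cv_folds", min = 0L),
    activation = match.arg(activation),
    probe_rule = match.arg(probe_rule),
    shuffle = check_flag(shuffle, "shuffle")
  )
  structure(cfg, class = "train_config")
}

# Batch values from either a batch_iterator element or a bare matrix.
batch_values <- function(batch) {
  if (is.list(batch) && !is.null(batch$values)) batch$values
  else if (is.matrix(batch)) batch
  else stop_metasem("`batch` must be a batch list or a matrix",
                    "metasem_arg_error")
}

#' Composite training loss on one batch
#'
#' `loss = L(X^p*, Y^p) + beta * sum(W1^2)` where `X^p*` is the blended
#' pseudo-label target (`0.5 * encoder(x) + x`), `Y^p` the meta-decoder's
#' SEM reconstruction, `L` mean squared error by default, and `W1` the
#' encoder's first-layer weights.
#'
#' @param params A `metasem_params` object.
#' @param grn A [weighted_grn()].
#' @param batch A batch from [batch_iterator()] (or a genes x cells matrix).
#' @param cfg A [train_config()].
#' @return A list `list(loss, fit, reg)` with `loss = fit + reg`.
#' @export
compute_loss <- function(params, grn, batch, cfg = train_config()) {
  x <- batch_values(batch)
  fb <- model_forward_backward(params, grn, x, cfg$beta, cfg$loss_kind)
  list(loss = fb$loss, fit = fb$fit, reg = fb$reg)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(tmpl) {
  zero <- rapply(tmpl, function(z) z * 0, how = "replace")
  list(m = zero, v = zero, t = 0L)
}

# One Adam step on a flat named list of tensors.
adam_update <- function(state, par, grads, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- state$t
  for (nm in names(par)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, par = par)
}

flat_sq_norm <- function(grads) {
  sum(rapply(grads, function(g) sum(g^2), how = "unlist"))
}

#' One bi-level training step on a batch
#'
#' Implements the one-step gradient probe: (a) loss and gradients at the
#' current parameters; (b) a single plain gradient-descent step of size
#' `lr_onestep` on encoder, decoder and adjacency forms the probe; (c) the
#' loss (and gradients) are recomputed at the probe; (d) if the probe
#' improves (loss drop by default, gradient-norm drop with
#' `probe_rule = "grad_norm"`), it is committed as the new starting point
#' and the Adam updates are applied there; otherwise the probe is discarded
#' and Adam updates the original parameters. The adjacency travels with the
#' decoder's optimizer and its diagonal is re-zeroed after every update.
#'
#' @param params A `metasem_params` object.
#' @param grn A [weighted_grn()].
#' @param batch A batch from [batch_iterator()] or a genes x cells matrix.
#' @param cfg A [train_config()].
#' @param opt_state Optimizer state from a previous call (`NULL` starts
#'   fresh Adam moments).
#' @param tgt_e Optional encoder feature matrix to use in the pseudo-label
#'   target (`NULL` uses the live encoder output). The training loop passes
#'   features snapshotted at training start so the objective is stationary.
#' @return A list `list(params, grn, accepted, loss, fit, opt_state)`;
#'   `loss` is the pre-update loss at the incoming parameters.
#' @export
inner_step <- function(params, grn, batch, cfg = train_config(),
                       opt_state = NULL, tgt_e = NULL) {
  x <- batch_values(batch)
  if (nrow(x) != length(grn$gene_ids)) {
    stop_metasem("batch gene dimension must match the GRN", "metasem_arg_error")
  }
  fb0 <- model_forward_backward(params, grn, x, cfg$beta, cfg$loss_kind,
                                tgt_e = tgt_e)

  probe <- params
  probe$encoder <- Map(function(p, g) p - cfg$lr_onestep * g,
                       params$encoder, fb0$grads$encoder)
  probe$decoder <- Map(function(p, g) p - cfg$lr_onestep * g,
                       params$decoder, fb0$grads$decoder)
  probe_A <- mask_diagonal(grn$weights - cfg$lr_onestep * fb0$grads$A)
  probe_grn <- grn; probe_grn$weights <- probe_A
  fb1 <- model_forward_backward(probe, probe_grn, x, cfg$beta, cfg$loss_kind,
                                tgt_e = tgt_e)

  accepted <- if (cfg$probe_rule == "loss") {
    fb1$loss < fb0$loss
  } else {
    flat_sq_norm(fb1$grads) < flat_sq_norm(fb0$grads)
  }

  if (accepted) {
    base_params <- probe; base_grn <- probe_grn; g <- fb1$grads
  } else {
    base_params <- params; base_grn <- grn; g <- fb0$grads
  }

  if (is.null(opt_state)) {
    opt_state <- list(
      encoder = adam_init(base_params$encoder),
      decoder = adam_init(base_params$decoder),
      A = adam_init(list(A = base_grn$weights))
    )
  }
  opt_state$encoder$t <- opt_state$encoder$t + 1L
  opt_state$decoder$t <- opt_state$decoder$t + 1L
  opt_state$A$t <- opt_state$A$t + 1L

  up_e <- adam_update(opt_state$encoder, base_params$encoder,
                      g$encoder, cfg$lr_encoder)
  up_d <- adam_update(opt_state$decoder, base_params$decoder,
                      g$decoder, cfg$lr_decoder)
  up_a <- adam_update(opt_state$A, list(A = base_grn$weights),
                      list(A = g$A), cfg$lr_decoder)
  opt_state$encoder <- up_e$state
  opt_state$decoder <- up_d$state
  opt_state$A <- up_a$state
  base_params$encoder <- up_e$par
  base_params$decoder <- up_d$par
  base_grn$weights <- mask_diagonal(up_a$par$A)

  list(params = base_params, grn = base_grn, accepted = accepted,
       loss = fb0$loss, fit = fb0$fit, opt_state = opt_state)
}

train_single <- function(expr, cfg, verbose = FALSE) {
  G <- length(expr$gene_ids)
  init <- init_model(G, hidden_dim = cfg$hidden_dim, seed = cfg$seed,
                     activation = cfg$activation, gene_ids = expr$gene_ids)
  params <- init$params
  grn <- init$grn
  opt_state <- NULL
  loss_history <- numeric(cfg$epochs)
  n_accepted <- 0L; n_steps <- 0L

  # Anchored pseudo-labels: the encoder features entering the blend target
  # are computed once from the initial parameters and held fixed, so the
  # whole run optimizes a stationary objective. A live (or per-epoch
  # refreshed) target lets the encoder inflate its own target faster than
  # the SEM reconstruction can follow, and the loss rises without bound.
  e_tgt <- encoder_forward_full(params, expr$values)$e

  for (epoch in seq_len(cfg$epochs)) {
    grn_epoch_start <- grn
    batches <- batch_iterator(expr, batch_size = cfg$batch_size,
                              shuffle = cfg$shuffle,
                              seed = (cfg$seed + epoch) %% .Machine$integer.max)
    epoch_loss <- 0; epoch_cells <- 0L
    for (batch in batches) {
      step <- inner_step(params, grn, batch, cfg, opt_state,
                         tgt_e = e_tgt[, batch$cell_indices, drop = FALSE])
      params <- step$params; grn <- step$grn; opt_state <- step$opt_state
      n_steps <- n_steps + 1L
      n_accepted <- n_accepted + as.integer(step$accepted)
      # batch losses are means per value, so the epoch mean weights each
      # batch by its cell count: every cell contributes exactly once
      nb <- length(batch$cell_indices)
      epoch_loss <- epoch_loss + step$loss * nb
      epoch_cells <- epoch_cells + nb
    }
    loss_history[epoch] <- epoch_loss / epoch_cells
    grn <- grn_layer_update(grn, grn_epoch_start, cfg$alpha)
    if (verbose) {
      message(sprintf("epoch %d/%d: loss %.6f, accepted %.2f",
                      epoch, cfg$epochs, loss_history[epoch],
                      n_accepted / n_steps))
    }
  }

  structure(list(grn = grn, params = params, loss_history = loss_history,
                 config = cfg,
                 accepted_probe_fraction = n_accepted / n_steps),
            class = "train_result")
}

#' Train the SEM network on an expression matrix
#'
#' Runs the full bi-level loop: per epoch, cells are split into batches and
#' each batch takes one [inner_step()]; at the end of every epoch the
#' GRN layer is refreshed by [grn_layer_update()] against the adjacency the
#' epoch started from. The inferred network is read off the trained
#' adjacency (`result$grn`); edge scores are its absolute weights.
#'
#' With `cv_folds > 0`, cells are partitioned into folds and one model is
#' trained per fold on the remaining cells; a list of `train_result`
#' objects is returned.
#'
#' @param expr A preprocessed [expression_matrix()]
#'   (`normalization == "lognorm"`).
#' @param cfg A [train_config()].
#' @param verbose Emit a per-epoch progress message.
#' @return A `train_result` (or a list of them under cross-validation):
#'   `grn`, `params`, `loss_history`, `config`,
#'   `accepted_probe_fraction`.
#' @export
#' @examples
#' \donttest{
#' truth <- make_adjacency(sim_config(n_genes = 10, n_cells = 200, seed = 7))
#' expr <- simulate_expression(truth, sim_config(n_genes = 10, n_cells = 200,
#'                                               seed = 7))
#' fit <- train(expr, train_config(epochs = 5, seed = 7))
#' evaluate_grn(fit$grn, adjacency_to_truth(truth))
#' }
train <- function(expr, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!length(expr$gene_ids) || !length(expr$cell_ids)) {
    stop_metasem("empty expression matrix", "metasem_arg_error")
  }
  if (expr$normalization != "lognorm") {
    stop_metasem("train expects log-normalized expression (run preprocess first)",
                 "metasem_arg_error")
  }
  if (!inherits(cfg, "train_config")) {
    stop_metasem("`cfg` must be a train_config()", "metasem_arg_error")
  }

  if (cfg$cv_folds > 0L) {
    n <- length(expr$cell_ids)
    if (cfg$cv_folds > n) {
      stop_metasem("more folds than cells", "metasem_arg_error")
    }
    fold_of <- with_seed(cfg$seed, sample(rep_len(seq_len(cfg$cv_folds), n)))
    return(lapply(seq_len(cfg$cv_folds), function(f) {
      keep <- fold_of != f
      sub <- expression_matrix(expr$values[, keep, drop = FALSE],
                               normalization = expr$normalization)
      train_single(sub, cfg, verbose = verbose)
    }))
  }

  train_single(expr, cfg, verbose = verbose)
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d genes, %d epochs, final loss %.6f, probe acceptance %.2f\n",
              length(x$grn$gene_ids), length(x$loss_history),
              x$loss_history[length(x$loss_history)],
              x$accepted_probe_fraction))
  invisible(x)
}
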