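make_sim_expr <- function(n_genes = 10, n_cells = 200, seed = 7, ...) {
  cfg <- sim_config(n_genes = n_genes, n_cells = n_cells, seed = seed, ...)
  A <- make_adjacency(cfg)
  list(truth = A, expr = simulate_expression(A, cfg), cfg = cfg)
}

test_that("compute_loss decomposes into fit and regularization exactly", {
  init <- tiny_model(G = 3, hidden_dim = 4)
  x <- withr::with_seed(5, matrix(rnorm(12), 3, 4))
  batch <- list(values = x, cell_indices = 1:4)

  cfg0 <- train_config(hidden_dim = 4, beta = 0)
  l0 <- compute_loss(init$params, init$grn, batch, cfg0)
  expect_identical(l0$loss, l0$fit)
  expect_identical(l0$reg, 0)

  cfg5 <- train_config(hidden_dim = 4, beta = 0.5)
  l5 <- compute_loss(init$params, init$grn, batch, cfg5)
  expect_equal(l5$loss, l5$fit + 0.5 * sum(init$params$encoder$w1^2),
               tolerance = 1e-14)

  # mean-squared fit term by hand: target [1, 2], prediction [0, 0] -> 2.5;
  # a zero encoder makes the blend target equal x, a zero decoder predicts 0
  zero <- tiny_model(G = 2, hidden_dim = 2)
  zero$params$encoder <- rapply(zero$params$encoder, function(w) w * 0,
                                how = "replace")
  zero$params$decoder <- rapply(zero$params$decoder, function(w) w * 0,
                                how = "replace")
  hand <- compute_loss(zero$params, zero$grn, matrix(c(1, 2), 2, 1),
                       train_config(hidden_dim = 2, beta = 0))
  expect_equal(hand$fit, 2.5)
})

test_that("the loss responds to beta exactly by sum of squared first-layer weights", {
  init <- tiny_model(G = 4, hidden_dim = 6)
  x <- withr::with_seed(6, matrix(rnorm(20), 4, 5))
  w1sq <- sum(init$params$encoder$w1^2)
  delta <- 0.37
  la <- compute_loss(init$params, init$grn, x,
                     train_config(hidden_dim = 6, beta = 0.1))
  lb <- compute_loss(init$params, init$grn, x,
                     train_config(hidden_dim = 6, beta = 0.1 + delta))
  expect_equal(lb$loss - la$loss, delta * w1sq, tolerance = 1e-12)
})

test_that("inner_step probes with a plain gradient step and is a no-op at zero rates", {
  sim <- make_sim_expr()
  batch <- batch_iterator(sim$expr, 64)[[1]]
  init <- init_model(10, hidden_dim = 16, seed = 1,
                     gene_ids = sim$expr$gene_ids)

  frozen <- train_config(hidden_dim = 16, lr_encoder = 0, lr_decoder = 0,
                         lr_onestep = 0)
  st <- inner_step(init$params, init$grn, batch, frozen)
  expect_identical(st$params$encoder, init$params$encoder)
  expect_identical(st$grn$weights, init$grn$weights)
  expect_false(st$accepted) # zero-length probe cannot strictly improve

  # the probe is exactly params - lr_onestep * grad
  cfg <- train_config(hidden_dim = 16, lr_onestep = 1e-2)
  fb <- metasem:::model_forward_backward(init$params, init$grn,
                                         batch$values, cfg$beta, "mse")
  st2 <- inner_step(init$params, init$grn, batch, cfg)
  if (st2$accepted) {
    # Adam moved from the probe; reconstruct the probe's first-layer weights
    probe_w1 <- init$params$encoder$w1 - 1e-2 * fb$grads$encoder$w1
    # after one Adam step of size lr the parameters move by at most ~lr
    expect_lt(max(abs(st2$params$encoder$w1 - probe_w1)),
              2 * cfg$lr_encoder)
  }

  # on a smooth objective a small probe step is accepted
  expect_true(st2$accepted)
  expect_equal(st2$loss, fb$loss)
})

test_that("gradient-norm probe rule runs and both rules make progress", {
  sim <- make_sim_expr(n_cells = 128)
  for (rule in c("loss", "grad_norm")) {
    cfg <- train_config(hidden_dim = 8, epochs = 3, seed = 2,
                        probe_rule = rule)
    res <- train(sim$expr, cfg)
    expect_true(all(is.finite(res$loss_history)))
    expect_lt(res$loss_history[3], res$loss_history[1])
  }
})

test_that("training is deterministic, frozen at zero rates, and loss descends", {
  sim <- make_sim_expr()

  frozen_cfg <- train_config(hidden_dim = 8, epochs = 1, lr_encoder = 0,
                             lr_decoder = 0, lr_onestep = 0, seed = 4)
  frozen <- train(sim$expr, frozen_cfg)
  init <- init_model(10, hidden_dim = 8, seed = 4,
                     gene_ids = sim$expr$gene_ids)
  # only the epoch-end convex blend of A with itself has happened
  expect_equal(frozen$grn$weights, init$grn$weights, tolerance = 1e-14)

  cfg <- train_config(hidden_dim = 16, epochs = 12, seed = 4)
  r1 <- train(sim$expr, cfg)
  r2 <- train(sim$expr, cfg)
  expect_identical(r1$loss_history, r2$loss_history)
  expect_identical(r1$grn$weights, r2$grn$weights)

  expect_lt(mean(tail(r1$loss_history, 3)), mean(head(r1$loss_history, 3)))
  expect_true(r1$accepted_probe_fraction >= 0 &&
              r1$accepted_probe_fraction <= 1)
})

test_that("disabling the probe degenerates to plain Adam and still converges", {
  sim <- make_sim_expr(n_cells = 128)
  plain <- train(sim$expr, train_config(hidden_dim = 8, epochs = 8,
                                        lr_onestep = 0, seed = 3))
  expect_equal(plain$accepted_probe_fraction, 0)
  expect_lt(mean(tail(plain$loss_history, 2)),
            mean(head(plain$loss_history, 2)))

  probed <- train(sim$expr, train_config(hidden_dim = 8, epochs = 8, seed = 3))
  expect_gt(probed$accepted_probe_fraction, 0)
})

test_that("epoch losses stay finite across seeds on simulator output", {
  for (seed in 1:5) {
    sim <- make_sim_expr(n_genes = 8, n_cells = 96, seed = seed)
    res <- train(sim$expr, train_config(hidden_dim = 8, epochs = 2,
                                        seed = seed))
    expect_true(all(is.finite(res$loss_history)))
    expect_true(all(diag(res$grn$weights) == 0))
  }
})

test_that("cross-validation returns one result per fold on distinct cell subsets", {
  sim <- make_sim_expr(n_genes = 6, n_cells = 60)
  res <- train(sim$expr, train_config(hidden_dim = 4, epochs = 2,
                                      cv_folds = 3, seed = 5))
  expect_length(res, 3)
  for (r in res) {
    expect_s3_class(r, "train_result")
    expect_length(r$loss_history, 2)
  }
})

test_that("bce loss trains without numerical failure", {
  sim <- make_sim_expr(n_genes = 6, n_cells = 64)
  res <- train(sim$expr, train_config(hidden_dim = 4, epochs = 2,
                                      loss_kind = "bce", seed = 6))
  expect_true(all(is.finite(res$loss_history)))
})

test_that("train validates its inputs", {
  sim <- make_sim_expr(n_genes = 6, n_cells = 30)
  raw <- expression_matrix(abs(sim$expr$values), normalization = "raw")
  expect_error(train(raw, train_config(epochs = 1)),
               class = "metasem_arg_error")
  expect_error(train(sim$expr, list(epochs = 1)),
               class = "metasem_arg_error")
})
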