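test_that("initialization is reproducible, zero-biased and zero-diagonal", {
  a <- init_model(5, hidden_dim = 8, seed = 42)
  b <- init_model(5, hidden_dim = 8, seed = 42)
  expect_identical(a$params, b$params)
  expect_identical(a$grn$weights, b$grn$weights)

  expect_true(all(diag(a$grn$weights) == 0))
  off <- a$grn$weights[row(a$grn$weights) != col(a$grn$weights)]
  expect_true(all(abs(off) <= 0.1))
  expect_true(all(a$params$encoder$b1 == 0))
  expect_true(all(a$params$decoder$c1 == 0))

  # minimal shape contract: hidden_dim 1, two genes
  tiny <- init_model(2, hidden_dim = 1, seed = 1)
  out <- encoder_forward(tiny$params, matrix(1:4, 2, 2))
  expect_equal(dim(out), c(2L, 2L))
  expect_error(init_model(1), class = "metasem_arg_error")
})

test_that("encoder_forward preserves shape, is pure and linear without activation", {
  init <- tiny_model(G = 3, hidden_dim = 4, activation = "linear")
  x <- matrix(rnorm(12), 3, 4)
  f1 <- encoder_forward(init$params, x)
  f2 <- encoder_forward(init$params, x)
  expect_identical(f1, f2)
  expect_equal(dim(f1), dim(x))

  # zero-bias linear channel: f(2x) == 2 f(x)
  expect_equal(encoder_forward(init$params, 2 * x), 2 * f1, tolerance = 1e-12)

  # all-zero weights give zero output
  zero <- init
  zero$params$encoder <- rapply(zero$params$encoder, function(w) w * 0,
                                how = "replace")
  expect_equal(encoder_forward(zero$params, x), x * 0)

  # hand-computed channel MLP, hidden_dim = 1, linear activation:
  # e = w3 * (W2 * (w1 * s + b1) + b2) + b3 for each scalar s
  hand <- init_model(2, hidden_dim = 1, seed = 2, activation = "linear")
  hand$params$encoder <- list(w1 = 0.5, b1 = 0.25, W2 = matrix(2), b2 = -0.5,
                              w3 = 3, b3 = 1)
  xs <- matrix(c(1, -2, 0.5, 4), 2, 2)
  expected <- 3 * (2 * (0.5 * xs + 0.25) - 0.5) + 1
  expect_equal(encoder_forward(hand$params, xs), expected, tolerance = 1e-12)
})

test_that("decoder_forward routes features through t(A) and scales linearly in A", {
  init <- tiny_model(G = 2, hidden_dim = 3, activation = "linear")
  xp <- matrix(c(1, 2, -1, 0.5), 2, 2)

  # A = 0 with zero-bias linear decoder: output 0
  zerod <- init
  zerod$params$decoder <- rapply(zerod$params$decoder, function(w) w * 0,
                                 how = "replace")
  A0 <- weighted_grn(matrix(0, 2, 2), init$grn$gene_ids)
  expect_equal(decoder_forward(zerod$params, A0, xp), xp * 0)

  # identity-like decoder (v2.v1 = 1, no bias) reproduces t(A) %*% xp
  ident <- init
  ident$params$decoder <- list(v1 = c(1, 0, 0), c1 = numeric(3),
                               v2 = c(1, 0, 0), c2 = 0)
  eps <- 0.01
  Ae <- weighted_grn(eps * (matrix(1, 2, 2) - diag(2)), init$grn$gene_ids)
  expect_equal(decoder_forward(ident$params, Ae, xp),
               unname(t(Ae$weights) %*% xp), tolerance = 1e-12)

  # doubling A doubles the output of a zero-bias linear decoder
  y1 <- decoder_forward(ident$params, Ae, xp)
  A2 <- weighted_grn(2 * Ae$weights, init$grn$gene_ids)
  expect_equal(decoder_forward(ident$params, A2, xp), 2 * y1,
               tolerance = 1e-12)

  expect_error(decoder_forward(init$params, Ae, matrix(0, 3, 2)),
               class = "metasem_arg_error")
})

test_that("grn_layer_update blends convexly and re-zeroes the diagonal", {
  B <- weighted_grn(matrix(1:9 / 10, 3, 3), paste0("g", 1:3))
  Zero <- weighted_grn(matrix(0, 3, 3), paste0("g", 1:3))

  expect_equal(grn_layer_update(B, Zero, alpha = 0)$weights, B$weights)
  expect_equal(grn_layer_update(B, Zero, alpha = 1)$weights, Zero$weights)

  B2 <- weighted_grn(2 * B$weights, paste0("g", 1:3))
  half <- grn_layer_update(B2, Zero, alpha = 0.5)
  expect_equal(half$weights, B$weights)
  expect_true(all(diag(half$weights) == 0))

  expect_error(grn_layer_update(B, Zero, alpha = 2),
               class = "metasem_arg_error")
  other <- weighted_grn(matrix(0, 3, 3), paste0("h", 1:3))
  expect_error(grn_layer_update(B, other), class = "metasem_arg_error")
})

test_that("feature_blend is 0.5 * encoder + xp", {
  init <- tiny_model(G = 3, hidden_dim = 4)
  x <- matrix(rnorm(9), 3, 3)
  enc <- encoder_forward(init$params, x)

  expect_equal(feature_blend(init$params, x, x * 0), 0.5 * enc)

  zero <- init
  zero$params$encoder <- rapply(zero$params$encoder, function(w) w * 0,
                                how = "replace")
  xp <- matrix(1, 3, 3)
  expect_equal(feature_blend(zero$params, x, xp), xp)

  # encoder output 2.0 everywhere (zero weights, b3 = 2) and xp 1.0 blend to 2.0
  const2 <- zero
  const2$params$encoder$b3 <- 2
  expect_equal(feature_blend(const2$params, x, xp), matrix(2, 3, 3))
  expect_error(feature_blend(init$params, x, matrix(0, 2, 2)),
               class = "metasem_arg_error")
})

test_that("mask_diagonal zeroes the diagonal and is idempotent", {
  expect_equal(mask_diagonal(diag(3)), matrix(0, 3, 3))
  ones <- mask_diagonal(matrix(1, 3, 3))
  expect_equal(sum(ones != 0), 6)
  expect_equal(mask_diagonal(ones), ones)
  g <- weighted_grn(matrix(rnorm(9), 3, 3))
  expect_identical(mask_diagonal(g), g)
})

test_that("analytic gradients match finite differences of the training objective", {
  # the pseudo-label target is detached, so finite differences are taken on
  # the frozen-target objective; the adjacency gradient needs no freezing
  init <- tiny_model(G = 3, hidden_dim = 4, seed = 2)
  x <- withr::with_seed(9, matrix(rnorm(9), 3, 3))
  beta <- 0.01
  fb <- metasem:::model_forward_backward(init$params, init$grn, x, beta, "mse")
  eps <- 1e-6

  # adjacency: central differences on the full loss
  num_A <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    up <- init$grn; up$weights[i, j] <- up$weights[i, j] + eps
    dn <- init$grn; dn$weights[i, j] <- dn$weights[i, j] - eps
    num_A[i, j] <-
      (metasem:::model_forward_backward(init$params, up, x, beta, "mse")$loss -
       metasem:::model_forward_backward(init$params, dn, x, beta, "mse")$loss) /
      (2 * eps)
  }
  expect_lt(max(abs(num_A - fb$grads$A)) / max(abs(num_A)), 1e-4)

  # encoder/decoder parameters against the frozen-target objective
  tgt0 <- 0.5 * encoder_forward(init$params, x) + x
  loss_frozen <- function(p) {
    yp <- decoder_forward(p, init$grn, encoder_forward(p, x))
    mean((tgt0 - yp)^2) + beta * sum(p$encoder$w1^2)
  }
  for (grp in c("encoder", "decoder")) {
    for (nm in names(init$params[[grp]])) {
      theta <- init$params[[grp]][[nm]]
      gnum <- theta * 0
      for (k in seq_along(theta)) {
        p_up <- init$params; p_up[[grp]][[nm]][k] <- theta[k] + eps
        p_dn <- init$params; p_dn[[grp]][[nm]][k] <- theta[k] - eps
        gnum[k] <- (loss_frozen(p_up) - loss_frozen(p_dn)) / (2 * eps)
      }
      ga <- fb$grads[[grp]][[nm]]
      expect_lt(max(abs(gnum - ga)) / max(max(abs(gnum)), 1e-10), 1e-4)
    }
  }
})
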