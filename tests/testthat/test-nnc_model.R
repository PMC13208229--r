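# analytic gradients of the composite loss against central finite differences
test_that("backpropagation matches numeric gradients through batch norm,
           dropout-free ReLU stacks, and the sigmoid output", {
  cfg <- nnc_config(encoder_dims = c(7, 5), latent_dim = 3,
                    dropout_rate = 0, lambda_marginal = 0.1)
  net <- nnc_network(4, cfg, seed = 3)
  U <- withr::with_seed(11L, matrix(runif(24), 6, 4))
  nl <- length(net$layers)
  lam <- 0.1
  loss_at <- function(net) {
    out <- nncopula:::net_forward(net, U, 1L, nl, training = TRUE)$out
    composite_loss(U, out, lam)$total
  }
  fw <- nncopula:::net_forward(net, U, 1L, nl, training = TRUE)
  cm <- colMeans(fw$out) - 0.5
  dOut <- 2 * (fw$out - U) / (6 * 4) + matrix(lam * 2 * cm / (4 * 6),
                                              6, 4, byrow = TRUE)
  grads <- nncopula:::net_backward(net, fw$caches, dOut, 1L, nl)
  eps <- 1e-6
  for (j in c(1, 2, nl - 1, nl)) {
    for (slot in c("W", "b")) {
      th <- net$layers[[j]][[slot]]
      idx <- seq_len(min(length(th), 6))
      for (i in idx) {
        np <- net; np$layers[[j]][[slot]][i] <- th[i] + eps
        nm <- net; nm$layers[[j]][[slot]][i] <- th[i] - eps
        num <- (loss_at(np) - loss_at(nm)) / (2 * eps)
        ana <- grads[[j]][[paste0("d", slot)]][i]
        expect_lt(abs(num - ana), 1e-7 + 1e-4 * abs(num))
      }
    }
    if (!is.null(net$layers[[j]]$bn)) {
      for (slot in c("gamma", "beta")) {
        th <- net$layers[[j]]$bn[[slot]]
        np <- net; np$layers[[j]]$bn[[slot]][1] <- th[1] + eps
        nm <- net; nm$layers[[j]]$bn[[slot]][1] <- th[1] - eps
        num <- (loss_at(np) - loss_at(nm)) / (2 * eps)
        ana <- grads[[j]][[paste0("d", slot)]][1]
        expect_lt(abs(num - ana), 1e-7 + 1e-4 * abs(num))
      }
    }
  }
})

test_that("encode and decode respect shapes, determinism, and range", {
  cfg <- nnc_config(encoder_dims = c(16, 8), latent_dim = 4)
  net <- nnc_network(6, cfg, seed = 1)
  U <- withr::with_seed(2L, matrix(runif(30), 5, 6))
  z1 <- nnc_encode(net, U)
  z2 <- nnc_encode(net, U)
  expect_identical(z1, z2)
  expect_identical(dim(z1), c(5L, 4L))
  expect_identical(dim(nnc_encode(net, U[1, , drop = FALSE])), c(1L, 4L))
  out <- nnc_decode(net, z1)
  expect_true(all(out > 0 & out < 1))
  expect_error(nnc_encode(net, U[, 1:3]), "columns")
  expect_error(nnc_decode(net, z1[, 1:2]), "columns")
  # zero weights: sigmoid(0) = 0.5 everywhere
  net0 <- net
  for (j in seq_along(net0$layers)) {
    net0$layers[[j]]$W[] <- 0
    net0$layers[[j]]$b[] <- 0
    if (!is.null(net0$layers[[j]]$bn)) net0$layers[[j]]$bn$beta[] <- 0
  }
  expect_equal(unname(nnc_decode(net0, z1 * 0)),
               matrix(0.5, 5, 6), tolerance = 1e-12)
})

test_that("composite loss decomposes as reconstruction plus weighted
           marginal penalty", {
  U <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2)
  same <- composite_loss(U, U, 0.1)
  expect_equal(same$recon, 0)
  expect_equal(same$total, 0.1 * same$marginal)
  flat <- composite_loss(matrix(0.5, 3, 1), matrix(0.4, 3, 1), 1)
  expect_equal(flat$marginal, 0.01)
  l0 <- composite_loss(U, U + 0.05, 0)
  expect_equal(l0$total, l0$recon)
  expect_gte(composite_loss(U, U + 0.1, 0.3)$total,
             composite_loss(U, U + 0.1, 0.3)$recon)
})

test_that("training reduces reconstruction error far below the untrained
           baseline and the logged losses decompose exactly", {
  U <- tiny_uniform_fixture(600, 10, seed = 33)
  cfg <- nnc_config(encoder_dims = c(64, 32), latent_dim = 10,
                    dropout_rate = 0, batch_size = 64,
                    early_stop_patience = 150L, lr_patience = 40L,
                    max_epochs = 150L)
  untrained <- nnc_network(10, cfg, seed = 8)
  mse0 <- mean((U - nnc_decode(untrained, nnc_encode(untrained, U)))^2)
  tr <- train_nnc(U, U, cfg, seed = 8)
  mse1 <- mean((U - nnc_decode(tr$net, nnc_encode(tr$net, U)))^2)
  expect_lt(mse1 * 10, mse0)
  with(tr$trace, expect_lt(
    max(abs(val_loss - (val_recon + cfg$lambda_marginal * val_marginal))),
    1e-7))
})

test_that("training is bitwise deterministic in the seed", {
  U <- tiny_uniform_fixture(240, 6, seed = 44)
  cfg <- nnc_config(encoder_dims = c(16, 8), latent_dim = 4,
                    max_epochs = 12L)
  t1 <- train_nnc(U[1:200, ], U[201:240, ], cfg, seed = 5)
  t2 <- train_nnc(U[1:200, ], U[201:240, ], cfg, seed = 5)
  expect_identical(t1$trace, t2$trace)
  expect_identical(t1$net, t2$net)
  t3 <- train_nnc(U[1:200, ], U[201:240, ], cfg, seed = 6)
  expect_false(identical(t3$trace$train_loss, t1$trace$train_loss))
})

test_that("the learning-rate schedule halves only after sustained plateaus
           and early stopping restores the best epoch", {
  model <- fixture_model()
  tr <- model$trace
  expect_true(all(diff(tr$lr) <= 0))
  # every halving must be preceded by lr_patience consecutive
  # non-improving epochs
  cfg <- model$config
  drops <- which(diff(tr$lr) < 0)
  best_so_far <- cummin(c(Inf, head(tr$val_loss, -1)))
  improved <- tr$val_loss < best_so_far - 1e-6
  for (e in drops) {
    expect_true(all(!improved[(e - cfg$lr_patience + 1):e]))
  }
  # stopped within patience of the best epoch, which is restored
  expect_lte(nrow(tr) - model$best_epoch, cfg$early_stop_patience)
  expect_equal(min(tr$val_loss), tr$val_loss[model$best_epoch])
  # validation loss at the retained epoch beats epoch 1
  expect_lt(tr$val_loss[model$best_epoch], tr$val_loss[1])
})

test_that("latent codes separate response-pattern clusters better than the
           raw pseudo-uniform rows", {
  n <- 400; K <- 12
  withr::with_seed(55L, {
    lab <- rep(0:1, each = n / 2)
    p_a <- c(rep(0.88, K / 2), rep(0.12, K / 2))
    p_b <- rev(p_a)
    P <- t(vapply(lab, function(l) if (l == 0) p_a else p_b, numeric(K)))
    Y <- matrix(rbinom(n * K, 1, P), n, K)
  })
  p_pool <- pmin(pmax(colMeans(Y), 0.02), 0.98)
  U <- randomized_pit(Y, p_pool, seed = 1)
  cfg <- nnc_config(encoder_dims = c(32, 16), latent_dim = 3,
                    max_epochs = 60L, early_stop_patience = 60L)
  tr <- train_nnc(U, U, cfg, seed = 2)
  Z <- nnc_encode(tr$net, U)
  mean_silhouette <- function(X, lab) {
    D <- as.matrix(dist(X))
    s <- vapply(seq_len(nrow(X)), function(i) {
      a <- mean(D[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
      b <- mean(D[i, lab != lab[i]])
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }
  expect_gt(mean_silhouette(Z, lab), mean_silhouette(U, lab))
})
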