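#' @section Architecture:
#' The dependence model is a deterministic autoencoder on the pseudo-uniform
#' matrix. The encoder stacks dense layers `K -> 256 -> 128 -> 64`, each
#' followed by batch normalization, a ReLU activation, and dropout, and ends
#' in a linear projection to `d` latent dimensions (no activation, so the
#' latent space spans all of R^d). The decoder mirrors the stack in reverse
#' (batch-normalized ReLU layers, but no dropout: regularization lives in
#' the encoder, so the decoder remains a sharp generative map) and ends in a
#' sigmoid output layer, constraining reconstructions to (0, 1) as the
#' copula representation requires.
#' @name nnc_network_architecture
#' @keywords internal
NULL

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

new_dense_layer <- function(n_in, n_out, act, bn, dropout) {
  # variance-scaled (He) initialization suited to rectified units
  W <- matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  list(W = W, b = rep(0, n_out),
       bn = if (bn) list(gamma = rep(1, n_out), beta = rep(0, n_out),
                         run_mean = rep(0, n_out), run_var = rep(1, n_out))
       else NULL,
       act = act, dropout = dropout)
}

#' Initialize an untrained autoencoder
#'
#' @param K Number of items (input/output width).
#' @param config An [nnc_config()] supplying `encoder_dims`, `latent_dim`,
#'   and `dropout_rate`.
#' @param seed Integer seed for the weight draws.
#' @return An object of class `nnc_network`.
#' @export
nnc_network <- function(K, config = nnc_config(), seed = 1L) {
  dims <- config$encoder_dims
  d <- config$latent_dim
  p <- config$dropout_rate
  withr::with_seed(as.integer(seed), {
    enc_sizes <- c(K, dims)
    layers <- list()
    for (i in seq_along(dims))
      layers[[length(layers) + 1L]] <-
        new_dense_layer(enc_sizes[i], enc_sizes[i + 1], "relu", TRUE, p)
    layers[[length(layers) + 1L]] <-
      new_dense_layer(dims[length(dims)], d, "linear", FALSE, 0)
    dec_sizes <- c(d, rev(dims))
    for (i in seq_along(dims))
      layers[[length(layers) + 1L]] <-
        new_dense_layer(dec_sizes[i], dec_sizes[i + 1], "relu", TRUE, 0)
    layers[[length(layers) + 1L]] <-
      new_dense_layer(dims[1], K, "sigmoid", FALSE, 0)
  })
  structure(list(layers = layers, K = K, d = d,
                 n_encoder = length(dims) + 1L),
            class = "nnc_network")
}

rowmat <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# forward pass through a contiguous run of layers; training mode uses batch
# statistics and dropout and returns the caches needed for backprop
net_forward <- function(net, X, from, to, training = FALSE) {
  caches <- vector("list", to - from + 1L)
  for (j in seq.int(from, to)) {
    ly <- net$layers[[j]]
    n <- nrow(X)
    Z <- X %*% ly$W + rowmat(ly$b, n)
    cache <- list(X_in = X)
    if (!is.null(ly$bn)) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(Z^2) - mu^2
        invstd <- 1 / sqrt(v + BN_EPS)
        Xhat <- (Z - rowmat(mu, n)) * rowmat(invstd, n)
        net$layers[[j]]$bn$run_mean <-
          (1 - BN_MOMENTUM) * ly$bn$run_mean + BN_MOMENTUM * mu
        net$layers[[j]]$bn$run_var <-
          (1 - BN_MOMENTUM) * ly$bn$run_var + BN_MOMENTUM * v
        cache$Xhat <- Xhat; cache$invstd <- invstd
      } else {
        Xhat <- (Z - rowmat(ly$bn$run_mean, n)) *
          rowmat(1 / sqrt(ly$bn$run_var + BN_EPS), n)
      }
      H <- Xhat * rowmat(ly$bn$gamma, n) + rowmat(ly$bn$beta, n)
    } else H <- Z
    A <- switch(ly$act,
                relu = pmax(H, 0),
                sigmoid = stats::plogis(H),
                linear = H)
    cache$H <- H; cache$A <- A
    if (training && ly$dropout > 0) {
      mask <- matrix(stats::runif(length(A)) >= ly$dropout,
                     nrow(A), ncol(A)) / (1 - ly$dropout)
      A <- A * mask
      cache$mask <- mask
    }
    caches[[j - from + 1L]] <- cache
    X <- A
  }
  list(out = X, caches = caches, net = net)
}

# backward pass matching net_forward(training = TRUE); returns gradients
# for layers from..to (same indexing as the caches)
net_backward <- function(net, caches, dOut, from, to) {
  grads <- vector("list", to - from + 1L)
  dA <- dOut
  for (j in seq.int(to, from)) {
    ly <- net$layers[[j]]
    cache <- caches[[j - from + 1L]]
    n <- nrow(dA)
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dH <- switch(ly$act,
                 relu = dA * (cache$H > 0),
                 sigmoid = dA * cache$A * (1 - cache$A),
                 linear = dA)
    g <- list()
    if (!is.null(ly$bn)) {
      Xhat <- cache$Xhat
      g$dgamma <- colSums(dH * Xhat)
      g$dbeta <- colSums(dH)
      dXhat <- dH * rowmat(ly$bn$gamma, n)
      s1 <- colSums(dXhat)
      s2 <- colSums(dXhat * Xhat)
      dZ <- rowmat(cache$invstd, n) / n *
        (n * dXhat - rowmat(s1, n) - Xhat * rowmat(s2, n))
    } else dZ <- dH
    g$dW <- crossprod(cache$X_in, dZ)
    g$db <- colSums(dZ)
    grads[[j - from + 1L]] <- g
    dA <- tcrossprod(dZ, ly$W)
  }
  grads
}

#' Encode pseudo-uniform rows to latent codes
#'
#' Runs the encoder in evaluation mode (stored batch-normalization
#' statistics, no dropout); deterministic given weights and input.
#'
#' @param net A trained or untrained `nnc_network`.
#' @param U Numeric matrix with `K` columns.
#' @return An n x d matrix of latent codes.
#' @export
nnc_encode <- function(net, U) {
  U <- as.matrix(U)
  if (ncol(U) != net$K)
    stop("input has ", ncol(U), " columns; network expects ", net$K)
  net_forward(net, U, 1L, net$n_encoder, training = FALSE)$out
}

#' Decode latent codes to pseudo-uniform reconstructions
#'
#' Runs the decoder in evaluation mode; the sigmoid output layer guarantees
#' every cell lies in (0, 1).
#'
#' @param net An `nnc_network`.
#' @param Z Numeric matrix with `d` columns.
#' @return An n x K matrix with entries in (0, 1).
#' @export
nnc_decode <- function(net, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != net$d)
    stop("codes have ", ncol(Z), " columns; network expects ", net$d)
  net_forward(net, Z, net$n_encoder + 1L, length(net$layers),
              training = FALSE)$out
}

#' Composite reconstruction + marginal-preservation loss
#'
#' `L = L_recon + lambda * L_marginal`, where `L_recon` is the mean squared
#' cell error between input and reconstruction and `L_marginal` penalizes
#' drift of the reconstructed column means away from 0.5, the mean of a
#' Uniform(0, 1) margin: `L_marginal = mean_k (colmean(U_hat)_k - 0.5)^2`.
#'
#' @param U Input pseudo-uniform matrix.
#' @param U_hat Reconstruction of the same shape.
#' @param lambda Nonnegative weight of the marginal term.
#' @return A list with `recon`, `marginal`, `lambda`, and `total`.
#' @export
composite_loss <- function(U, U_hat, lambda = 0.1) {
  stopifnot(all(dim(U) == dim(U_hat)), lambda >= 0)
  recon <- mean((U - U_hat)^2)
  marginal <- mean((colMeans(U_hat) - 0.5)^2)
  list(recon = recon, marginal = marginal, lambda = lambda,
       total = recon + lambda * marginal)
}

adam_init <- function(g) lapply(g, function(x) x * 0)

#' Train the autoencoder on pseudo-uniform data
#'
#' Minimizes the composite loss with Adam on shuffled mini-batches. After
#' every epoch the validation loss is evaluated in inference mode; the
#' learning rate is halved after `lr_patience` consecutive epochs without
#' improvement, training stops after `early_stop_patience` such epochs, and
#' the weights of the best-validation epoch are restored. The whole run is a
#' deterministic function of `(U_train, U_val, config, seed)`.
#'
#' @param U_train,U_val Pseudo-uniform matrices (train/validation rows).
#' @param config An [nnc_config()].
#' @param seed Integer seed governing initialization, shuffling, and dropout.
#' @return A list with `net` (the best-epoch `nnc_network`) and `trace`
#'   (data.frame: epoch, train_loss, val_loss, val_recon, val_marginal, lr),
#'   plus `best_epoch` and `stop_epoch`.
#' @export
train_nnc <- function(U_train, U_val, config = nnc_config(), seed = 42L) {
  U_train <- as.matrix(U_train); U_val <- as.matrix(U_val)
  K <- ncol(U_train)
  stopifnot(ncol(U_val) == K)
  lam <- config$lambda_marginal
  net <- nnc_network(K, config, seed = seed)
  n <- nrow(U_train)
  nl <- length(net$layers)
  moments <- NULL
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t_step <- 0L
  best_val <- Inf; best_net <- net; best_epoch <- 0L
  since_improve <- 0L; since_lr <- 0L
  trace <- NULL

  withr::with_seed(as.integer(seed) + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      epoch_loss <- 0; nb <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next  # batch norm needs >= 2 rows
        B <- length(idx)
        U <- U_train[idx, , drop = FALSE]
        fw <- net_forward(net, U, 1L, nl, training = TRUE)
        net <- fw$net  # running BN statistics advanced
        U_hat <- fw$out
        ls <- composite_loss(U, U_hat, lam)
        if (!is.finite(ls$total))
          stop("non-finite training loss at epoch ", epoch)
        epoch_loss <- epoch_loss + ls$total; nb <- nb + 1L
        cm <- colMeans(U_hat) - 0.5
        dOut <- 2 * (U_hat - U) / (B * K) +
          rowmat(lam * 2 * cm / (K * B), B)
        grads <- net_backward(net, fw$caches, dOut, 1L, nl)
        # Adam update over every trainable tensor
        t_step <- t_step + 1L
        bc1 <- 1 - beta1^t_step; bc2 <- 1 - beta2^t_step
        if (is.null(moments))
          moments <- lapply(grads, function(g)
            list(m = adam_init(g), v = adam_init(g)))
        for (j in seq_len(nl)) {
          g <- grads[[j]]
          for (nm in names(g)) {
            moments[[j]]$m[[nm]] <-
              beta1 * moments[[j]]$m[[nm]] + (1 - beta1) * g[[nm]]
            moments[[j]]$v[[nm]] <-
              beta2 * moments[[j]]$v[[nm]] + (1 - beta2) * g[[nm]]^2
            upd <- lr * (moments[[j]]$m[[nm]] / bc1) /
              (sqrt(moments[[j]]$v[[nm]] / bc2) + adam_eps)
            tgt <- switch(nm, dW = "W", db = "b",
                          dgamma = "gamma", dbeta = "beta")
            if (tgt %in% c("gamma", "beta"))
              net$layers[[j]]$bn[[tgt]] <- net$layers[[j]]$bn[[tgt]] - upd
            else net$layers[[j]][[tgt]] <- net$layers[[j]][[tgt]] - upd
          }
        }
      }
      val_hat <- net_forward(net, U_val, 1L, nl, training = FALSE)$out
      vl <- composite_loss(U_val, val_hat, lam)
      trace <- rbind(trace, data.frame(
        epoch = epoch, train_loss = epoch_loss / nb, val_loss = vl$total,
        val_recon = vl$recon, val_marginal = vl$marginal, lr = lr))
      if (vl$total < best_val - 1e-6) {
        best_val <- vl$total; best_net <- net; best_epoch <- epoch
        since_improve <- 0L; since_lr <- 0L
      } else {
        since_improve <- since_improve + 1L
        since_lr <- since_lr + 1L
      }
      if (since_lr >= config$lr_patience) {
        lr <- lr * config$lr_factor
        since_lr <- 0L
      }
      if (since_improve >= config$early_stop_patience) break
    }
  })
  list(net = best_net, trace = trace, best_epoch = best_epoch,
       stop_epoch = nrow(trace))
}
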