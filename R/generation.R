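#' Train the full neural network copula generator
#'
#' End-to-end model construction from binary training and validation data:
#' (1) training-partition marginal probabilities `p_hat` are recorded;
#' (2) both partitions are mapped to pseudo-uniform matrices by the
#' randomized probability integral transform, always using the training
#' `p_hat` (drawn once, so the training objective is stationary);
#' (3) the autoencoder is trained on the training rows with early stopping
#' against the validation rows; (4) a Gaussian KDE is fitted to the encoder's
#' latent codes of the training rows. The returned object is the complete
#' generative artifact.
#'
#' @param Y_train,Y_val Binary response matrices (same items).
#' @param config An [nnc_config()].
#' @param seed Master seed for the run; the PIT draw, network training, and
#'   any downstream generation seeds are derived from it deterministically.
#' @return An object of class `nnc_model` with fields `net`, `p_hat`, `kde`,
#'   `config`, `trace`, `seed`, and `n_train`.
#' @export
nnc_train <- function(Y_train, Y_val, config = nnc_config(),
                      seed = config$master_seed) {
  Y_train <- validate_response_matrix(Y_train)
  Y_val <- validate_response_matrix(Y_val)
  if (ncol(Y_train) != ncol(Y_val))
    stop("train and validation matrices must share items")
  p_hat <- colMeans(Y_train)
  if (any(p_hat <= 0 | p_hat >= 1))
    stop("degenerate training item(s): ",
         paste(colnames(Y_train)[p_hat <= 0 | p_hat >= 1], collapse = ", "))
  seeds <- spawn_seeds(seed, 3L)
  U_train <- randomized_pit(Y_train, p_hat, seed = seeds[1])
  U_val <- randomized_pit(Y_val, p_hat, seed = seeds[2])
  fit <- train_nnc(U_train, U_val, config, seed = seeds[3])
  codes <- nnc_encode(fit$net, U_train)
  kde <- fit_kde(codes, h = config$kde_bandwidth)
  structure(list(net = fit$net, p_hat = p_hat, kde = kde, config = config,
                 trace = fit$trace, best_epoch = fit$best_epoch,
                 seed = as.integer(seed), n_train = nrow(Y_train)),
            class = "nnc_model")
}

#' @export
print.nnc_model <- function(x, ...) {
  cat("Neural network copula model:", length(x$p_hat), "items, trained on",
      x$n_train, "examinees\n")
  cat("  best epoch", x$best_epoch, "of", nrow(x$trace),
      "| val loss", format(min(x$trace$val_loss), digits = 6), "\n")
  cat("  latent d =", x$net$d, "| kde h =", x$kde$h,
      "(Silverman ref", format(x$kde$h_silverman, digits = 3), ")\n")
  invisible(x)
}

#' Generate a synthetic binary response matrix
#'
#' Samples `m` latent codes from the fitted kernel density, decodes them to
#' pseudo-uniform rows (decoder in evaluation mode), and applies the inverse
#' threshold transform at the training marginals `p_hat`, which preserves
#' item difficulty by construction.
#'
#' @param model An `nnc_model` from [nnc_train()].
#' @param m Number of synthetic examinees (defaults to the training n).
#' @param seed Integer seed; the same `(model, m, seed)` always yields the
#'   identical matrix.
#' @return An m x K binary matrix.
#' @export
nnc_generate <- function(model, m = model$n_train, seed = 1L) {
  stopifnot(inherits(model, "nnc_model"), m >= 1)
  z <- sample_kde(model$kde, m, seed = seed)
  U <- nnc_decode(model$net, z)
  Y <- inverse_pit(U, model$p_hat)
  colnames(Y) <- names(model$p_hat)
  Y
}

#' Generate a batch of independent synthetic datasets
#'
#' Replication `r` uses the `r`-th child seed derived from `master_seed`, so
#' the batch is reproducible as a whole while replications are mutually
#' independent given the model.
#'
#' @param model An `nnc_model`.
#' @param m Examinees per replication.
#' @param M Number of replications.
#' @param master_seed Master seed for the child-seed sequence.
#' @return A list of `M` binary matrices.
#' @export
nnc_generate_batch <- function(model, m = model$n_train, M,
                               master_seed = 1L) {
  stopifnot(M >= 1)
  seeds <- spawn_seeds(master_seed, M)
  lapply(seeds, function(s) nnc_generate(model, m, seed = s))
}
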