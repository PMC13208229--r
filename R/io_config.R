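#' Run configuration for the neural network copula pipeline
#'
#' Collects every tunable of the training/generation pipeline into a single
#' validated list. Defaults reproduce the reference configuration: a
#' three-hidden-layer encoder \code{[256, 128, 64]}, dropout 0.2, marginal
#' penalty weight \code{lambda = 0.1}, Adam with initial learning rate 0.001
#' and mini-batches of 64, plateau learning-rate halving after 10 stalled
#' epochs, early stopping after 20, latent dimension 20 and kernel bandwidth
#' 0.2, and a 64/16/20 train/validation/test split.
#'
#' @param encoder_dims Integer vector of hidden-layer widths for the encoder
#'   (mirrored by the decoder).
#' @param latent_dim Dimension \code{d} of the latent code.
#' @param dropout_rate Dropout probability in `[0, 1)` applied after each
#'   hidden activation during training.
#' @param lambda_marginal Nonnegative weight of the marginal-preservation loss.
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param lr_patience Epochs of non-improving validation loss before the
#'   learning rate is halved.
#' @param lr_factor Multiplicative learning-rate decay factor.
#' @param early_stop_patience Epochs of non-improving validation loss before
#'   training stops (best weights are restored).
#' @param max_epochs Hard cap on training epochs.
#' @param kde_bandwidth Isotropic Gaussian KDE bandwidth \code{h} used when
#'   sampling latent codes.
#' @param partition_fractions Length-3 numeric vector of train/validation/test
#'   fractions summing to 1.
#' @param master_seed Integer master seed for the run.
#' @param n_mc_replications Number of Monte-Carlo replications \code{M} for the
#'   inferential-precision facet.
#'
#' @return An object of class \code{nnc_config} (a named list).
#' @export
nnc_config <- function(encoder_dims = c(256L, 128L, 64L),
                       latent_dim = 20L,
                       dropout_rate = 0.2,
                       lambda_marginal = 0.1,
                       learning_rate = 0.001,
                       batch_size = 64L,
                       lr_patience = 10L,
                       lr_factor = 0.5,
                       early_stop_patience = 20L,
                       max_epochs = 500L,
                       kde_bandwidth = 0.2,
                       partition_fractions = c(0.64, 0.16, 0.20),
                       master_seed = 42L,
                       n_mc_replications = 500L) {
  encoder_dims <- as.integer(encoder_dims)
  if (length(encoder_dims) < 1L || any(encoder_dims <= 0L))
    stop("encoder_dims must be a vector of strictly positive integers")
  latent_dim <- as.integer(latent_dim)
  if (latent_dim < 1L) stop("latent_dim must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (lambda_marginal < 0) stop("lambda_marginal must be nonnegative")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be a positive integer")
  if (lr_factor <= 0 || lr_factor >= 1) stop("lr_factor must lie in (0, 1)")
  if (kde_bandwidth <= 0) stop("kde_bandwidth must be positive")
  if (length(partition_fractions) != 3L || any(partition_fractions < 0))
    stop("partition_fractions must be three nonnegative numbers")
  if (abs(sum(partition_fractions) - 1) > 1e-9)
    stop("partition_fractions must sum to 1")
  structure(list(
    encoder_dims = encoder_dims,
    latent_dim = latent_dim,
    dropout_rate = dropout_rate,
    lambda_marginal = lambda_marginal,
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    lr_patience = as.integer(lr_patience),
    lr_factor = lr_factor,
    early_stop_patience = as.integer(early_stop_patience),
    max_epochs = as.integer(max_epochs),
    kde_bandwidth = kde_bandwidth,
    partition_fractions = partition_fractions,
    master_seed = as.integer(master_seed),
    n_mc_replications = as.integer(n_mc_replications)
  ), class = "nnc_config")
}

#' @export
print.nnc_config <- function(x, ...) {
  cat("Neural network copula run configuration\n")
  cat("  encoder dims :", paste(x$encoder_dims, collapse = " -> "),
      "-> d =", x$latent_dim, "\n")
  cat("  dropout", x$dropout_rate, "| lambda", x$lambda_marginal,
      "| lr", x$learning_rate, "| batch", x$batch_size, "\n")
  cat("  lr patience", x$lr_patience, "x", x$lr_factor,
      "| early stop", x$early_stop_patience,
      "| max epochs", x$max_epochs, "\n")
  cat("  kde bandwidth h =", x$kde_bandwidth,
      "| partitions", paste(x$partition_fractions, collapse = "/"), "\n")
  cat("  master seed", x$master_seed,
      "| MC replications", x$n_mc_replications, "\n")
  invisible(x)
}

#' Read a binary response matrix from CSV
#'
#' The expected format is a UTF-8 CSV with one header row of item labels and
#' one row per examinee; every cell must be 0 or 1 and every row must have the
#' same length. Missing or non-binary cells are rejected with an error naming
#' the offending row and column.
#'
#' @param path Path to the CSV file.
#' @return An integer matrix (examinees x items) with item labels as column
#'   names.
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 1L) stop("response CSV has no columns: ", path)
  m <- as.matrix(df)
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("non-binary cell '%s' at row %d, column '%s' in %s",
                 m[i, j], i, colnames(df)[j], path))
  }
  y <- matrix(as.integer(num), nrow = nrow(m),
              dimnames = list(NULL, colnames(df)))
  y
}

#' Write a binary response matrix to CSV
#'
#' Inverse of [read_response_matrix()]; the round trip is lossless.
#'
#' @param Y Binary response matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(Y, path) {
  Y <- validate_response_matrix(Y)
  utils::write.csv(as.data.frame(Y), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @keywords internal
validate_response_matrix <- function(Y) {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (any(is.na(Y)))
    stop("response matrix contains missing cells; complete data required")
  if (!all(Y %in% c(0L, 1L)))
    stop("response matrix must be strictly binary (0/1)")
  storage.mode(Y) <- "integer"
  if (is.null(colnames(Y)))
    colnames(Y) <- sprintf("item%02d", seq_len(ncol(Y)))
  Y
}

#' Derive reproducible child seeds from a master seed
#'
#' Child seeds are a deterministic function of the master seed: the same
#' master always yields the identical ordered sequence, and seeds within a
#' call are distinct (drawn without replacement from the positive 32-bit
#' integers). The caller's RNG state is left untouched.
#'
#' @param master Integer master seed.
#' @param count Number of child seeds (>= 1).
#' @return Integer vector of length `count`.
#' @export
spawn_seeds <- function(master, count) {
  stopifnot(count >= 1)
  withr::with_seed(as.integer(master),
                   sample.int(.Machine$integer.max, as.integer(count)))
}

#' Stratified train/validation/test partition by total-score decile
#'
#' Rows are stratified by deciles of the pooled total score (deciles computed
#' once on the full sample; ties at a decile boundary fall in the lower
#' stratum) and allocated to the subsets proportionally within each stratum,
#' so every subset preserves the pooled score distribution. Strata too small
#' to honour the fractions fall back to a simple random allocation for their
#' rows, with a message.
#'
#' @param Y Binary response matrix with at least 10 rows.
#' @param fractions Numeric vector of subset fractions summing to 1
#'   (default 0.64/0.16/0.20).
#' @param seed Integer seed controlling the within-stratum shuffles.
#' @return A list of disjoint, exhaustive response matrices (one per
#'   fraction), with an attribute `"rows"` giving the original row indices.
#' @export
stratified_partition <- function(Y, fractions = c(0.64, 0.16, 0.20),
                                 seed = 42L) {
  Y <- validate_response_matrix(Y)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- nrow(Y)
  if (n < 10L) stop("need at least 10 rows to stratify by decile")
  score <- rowSums(Y)
  qs <- unique(stats::quantile(score, probs = seq(0, 1, 0.1), names = FALSE))
  stratum <- if (length(qs) > 1L) {
    cut(score, breaks = qs, include.lowest = TRUE, right = TRUE,
        labels = FALSE)
  } else rep(1L, n)
  nsub <- length(fractions)
  assign <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (s in unique(stratum)) {
      rows <- which(stratum == s)
      ns <- length(rows)
      rows <- rows[sample.int(ns)]
      if (ns < nsub) {
        message("stratum ", s, " has ", ns,
                " rows (< ", nsub, " subsets): simple random allocation")
        assign[rows] <- sample.int(nsub, ns)
        next
      }
      # largest-remainder apportionment of ns rows to the fractions
      raw <- fractions * ns
      cnt <- floor(raw)
      rem <- ns - sum(cnt)
      if (rem > 0) {
        extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[extra] <- cnt[extra] + 1
      }
      assign[rows] <- rep.int(seq_len(nsub), cnt)
    }
  })
  out <- lapply(seq_len(nsub), function(k) {
    idx <- which(assign == k)
    m <- Y[idx, , drop = FALSE]
    attr(m, "rows") <- idx
    m
  })
  names(out) <- if (nsub == 3L) c("train", "validation", "test") else
    paste0("subset", seq_len(nsub))
  out
}
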