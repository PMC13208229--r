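#' Randomized probability integral transform of binary responses
#'
#' Maps each binary response to a pseudo-uniform variate: a correct response
#' to item k is replaced by a uniform draw on `(1 - p_k, 1)`, an incorrect
#' one by a draw on `(0, 1 - p_k)`, where `p_k` is the item's marginal
#' probability of a correct response. Marginally each column is then exactly
#' Uniform(0, 1) while inter-item dependence is preserved — the continuity
#' correction a copula representation of discrete margins requires. Draws
#' exclude the interval endpoints, so [inverse_pit()] with the same `p`
#' recovers the binary matrix exactly.
#'
#' @param Y Binary response matrix.
#' @param p Marginal probabilities, strictly inside (0, 1), length `ncol(Y)`.
#'   Defaults to the column means of `Y`; for validation/test rows pass the
#'   training-partition proportions.
#' @param seed Integer seed for the uniform draws.
#' @return An n x K numeric matrix with values in (0, 1).
#' @export
randomized_pit <- function(Y, p = colMeans(Y), seed = 1L) {
  Y <- validate_response_matrix(Y)
  if (length(p) != ncol(Y)) stop("p must have one entry per item")
  if (any(p <= 0 | p >= 1))
    stop("marginal probabilities must lie strictly inside (0, 1)")
  n <- nrow(Y); K <- ncol(Y)
  eps <- .Machine$double.eps
  U <- withr::with_seed(as.integer(seed),
                        matrix(stats::runif(n * K, eps, 1 - eps), n, K))
  thr <- matrix(1 - p, n, K, byrow = TRUE)
  # scale the raw uniform into the sub-interval selected by the response
  out <- ifelse(Y == 1L, thr + U * (1 - thr), U * thr)
  dimnames(out) <- dimnames(Y)
  out
}

#' Inverse threshold transform from pseudo-uniform to binary
#'
#' `Y_ik = 1{ U_ik > 1 - p_k }` (strict inequality; a value exactly at the
#' threshold maps to 0). If a column of `U` is Uniform(0, 1) the expected
#' column mean of `Y` equals `p_k`, so item difficulty is preserved by
#' construction.
#'
#' @param U Numeric matrix with values in `[0, 1]`.
#' @param p Marginal probabilities per column.
#' @return Binary integer matrix of the same shape.
#' @export
inverse_pit <- function(U, p) {
  U <- as.matrix(U)
  if (length(p) != ncol(U)) stop("p must have one entry per column of U")
  if (any(U < 0 | U > 1)) stop("U must lie in [0, 1]")
  Y <- matrix(as.integer(U > matrix(1 - p, nrow(U), ncol(U), byrow = TRUE)),
              nrow(U), ncol(U))
  dimnames(Y) <- dimnames(U)
  Y
}
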