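#' 2PL item response probability
#'
#' `P(Y = 1 | theta) = 1 / (1 + exp(-a (theta - b)))`: the probability that
#' an examinee with ability `theta` answers an item with discrimination `a`
#' and difficulty `b` correctly. Strictly increasing in `theta`, equal to
#' 0.5 at `theta = b`.
#'
#' @param theta Ability value(s).
#' @param a Discrimination (> 0).
#' @param b Difficulty.
#' @return Probabilities in (0, 1), vectorized over `theta`.
#' @export
two_pl_probability <- function(theta, a, b) {
  if (any(a <= 0)) stop("discrimination a must be positive")
  stats::plogis(a * (theta - b))
}

#' 2PL item information
#'
#' `I_k(theta) = a^2 P (1 - P)`, the Fisher information an item contributes
#' about ability; maximized at `theta = b` with value `a^2 / 4`.
#'
#' @inheritParams two_pl_probability
#' @return Nonnegative information values, vectorized over `theta`.
#' @export
item_information <- function(theta, a, b) {
  p <- two_pl_probability(theta, a, b)
  a^2 * p * (1 - p)
}

#' Default ability evaluation grid
#'
#' 100 equally spaced points on `[-4, 4]` (endpoints included), the grid on
#' which information and conditional standard error profiles are evaluated.
#'
#' @param n_points Number of grid points.
#' @param lower,upper Grid endpoints.
#' @return Strictly increasing numeric vector.
#' @export
ability_grid <- function(n_points = 100L, lower = -4, upper = 4) {
  stopifnot(n_points >= 2L, upper > lower)
  seq(lower, upper, length.out = n_points)
}

#' Test information function and conditional standard error of measurement
#'
#' Evaluates each item's information on an ability grid, sums them into the
#' test information function `I(theta) = sum_k I_k(theta)`, and transforms it
#' into the conditional standard error of measurement
#' `CSEM(theta) = 1 / sqrt(I(theta))`.
#'
#' @param a,b Numeric vectors of item parameters (equal length `K >= 1`).
#' @param grid Ability grid (default [ability_grid()]).
#' @return A data.frame with columns `theta`, one `info_<label>` column per
#'   item, `tif`, and `csem`.
#' @export
test_information_and_csem <- function(a, b, grid = ability_grid()) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  K <- length(a)
  info <- vapply(seq_len(K), function(k) item_information(grid, a[k], b[k]),
                 numeric(length(grid)))
  tif <- rowSums(info)
  if (any(tif <= 0))
    stop("test information vanished on the grid; check item parameters")
  out <- data.frame(theta = grid, info,
                    tif = tif, csem = 1 / sqrt(tif))
  names(out)[1 + seq_len(K)] <- sprintf("info_item%02d", seq_len(K))
  out
}
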