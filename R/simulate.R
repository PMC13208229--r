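#' Simulation design for 2PL response data
#'
#' Describes a ground-truth two-parameter logistic (2PL) test: item
#' discriminations `a` (positive), difficulties `b`, abilities drawn from
#' N(0, 1), and an optional testlet structure inducing local dependence.
#' When item parameters are not supplied they are drawn once (seeded) from
#' distributions spanning the range typical of operational numerical
#' reasoning assessments: `a` log-normal(0, 0.5) truncated to `[0.5, 3.5]`
#' and `b` standard normal truncated to `[-2.5, 2.5]`.
#'
#' @param n Number of examinees.
#' @param K Number of items.
#' @param a Optional numeric vector of discriminations (length `K`).
#' @param b Optional numeric vector of difficulties (length `K`).
#' @param testlets Optional integer vector of length `K` mapping items to
#'   testlet clusters; `NULL` means strict local independence.
#' @param gamma Testlet effect standard deviation (>= 0); 0 recovers local
#'   independence.
#' @param seed Integer seed used both for any parameter draws and, by
#'   default, for response generation.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n, K, a = NULL, b = NULL, testlets = NULL,
                       gamma = 0, seed = 1L) {
  stopifnot(n >= 1, K >= 1, gamma >= 0)
  seed <- as.integer(seed)
  if (is.null(a) || is.null(b)) {
    drawn <- withr::with_seed(seed, {
      list(a = rtrunc(K, function(m) stats::rlnorm(m, 0, 0.5), 0.5, 3.5),
           b = rtrunc(K, function(m) stats::rnorm(m), -2.5, 2.5))
    })
    if (is.null(a)) a <- drawn$a
    if (is.null(b)) b <- drawn$b
  }
  if (length(a) != K || length(b) != K)
    stop("a and b must have length K")
  if (any(a <= 0)) stop("all discriminations a must be positive")
  if (!is.null(testlets)) {
    if (length(testlets) != K) stop("testlets must map all K items")
    testlets <- as.integer(factor(testlets))
  }
  structure(list(n = as.integer(n), K = as.integer(K), a = as.numeric(a),
                 b = as.numeric(b), testlets = testlets, gamma = gamma,
                 seed = seed),
            class = "sim_design")
}

# rejection-free truncated sampling by redraw (ranges are wide; loop is short)
#' @keywords internal
rtrunc <- function(k, rfun, lo, hi) {
  x <- rfun(k)
  for (it in 1:100) {
    out <- x < lo | x > hi
    if (!any(out)) break
    x[out] <- rfun(sum(out))
  }
  pmin(pmax(x, lo), hi)
}

#' Simulate 2PL binary responses
#'
#' Draws abilities from N(0, 1) and responses from
#' `P(Y = 1 | theta) = logistic(a * (theta - b))`. With a testlet map, the
#' ability entering item k is `theta_i + gamma * u_{i, c(k)}` with
#' examinee-by-cluster effects `u ~ N(0, 1)`, which induces extra
#' within-testlet dependence while leaving gamma = 0 as strict local
#' independence.
#'
#' @param design A [sim_design()].
#' @param seed Optional seed overriding `design$seed` for the response draw.
#' @return A list with `Y` (n x K integer matrix), `a`, `b`, `theta`, and
#'   (when testlets are present) the cluster effects `u`.
#' @export
simulate_2pl <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "sim_design"))
  n <- design$n; K <- design$K
  withr::with_seed(as.integer(seed), {
    theta <- stats::rnorm(n)
    eff <- theta %o% rep(1, K)
    u <- NULL
    if (!is.null(design$testlets) && design$gamma > 0) {
      ncl <- max(design$testlets)
      u <- matrix(stats::rnorm(n * ncl), n, ncl)
      eff <- eff + design$gamma * u[, design$testlets, drop = FALSE]
    }
    P <- stats::plogis(sweep(eff, 2, design$b, "-") %*%
                         diag(design$a, K, K))
    Y <- matrix(as.integer(stats::runif(n * K) < P), n, K)
  })
  colnames(Y) <- sprintf("item%02d", seq_len(K))
  list(Y = Y, a = design$a, b = design$b, theta = theta, u = u)
}

#' Population marginal probability of a correct response
#'
#' Integrates the 2PL item response function against the standard normal
#' ability density by Gauss-Hermite quadrature:
#' `p = integral logistic(a (theta - b)) phi(theta) d theta`.
#'
#' @param a Discrimination (> 0); vectorized over items.
#' @param b Difficulty; recycled against `a`.
#' @param n_nodes Number of quadrature nodes.
#' @return Probabilities in `[0, 1]`.
#' @export
population_marginal <- function(a, b, n_nodes = 61L) {
  if (any(a <= 0)) stop("a must be positive")
  q <- gh_quadrature(n_nodes)
  k <- max(length(a), length(b))
  a <- rep_len(a, k); b <- rep_len(b, k)
  vapply(seq_len(k), function(j) {
    sum(q$weights * stats::plogis(a[j] * (q$nodes - b[j])))
  }, numeric(1))
}
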