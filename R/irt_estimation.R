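#' Gauss-Hermite quadrature for the standard normal ability prior
#'
#' Returns nodes and weights approximating integration against the N(0, 1)
#' density: physicists' Gauss-Hermite nodes rescaled by `sqrt(2)` with
#' weights normalized by `1/sqrt(pi)`. Weights sum to 1 and reproduce the
#' prior variance to machine precision.
#'
#' @param n_nodes Number of nodes (default 41).
#' @return A list with `nodes` and `weights`.
#' @export
gh_quadrature <- function(n_nodes = 41L) {
  stopifnot(n_nodes >= 2L)
  g <- pracma::gaussHermite(as.integer(n_nodes))
  list(nodes = sqrt(2) * g$x, weights = g$w / sqrt(pi))
}

# log-likelihood of every response pattern at every quadrature node,
# n x Q, via two matrix products
pattern_loglik <- function(Y, a, b, nodes) {
  eta <- outer(-b, nodes, "+") * a          # K x Q: a_k (theta_q - b_k)
  logP <- stats::plogis(eta, log.p = TRUE)
  log1mP <- stats::plogis(-eta, log.p = TRUE)
  Y %*% logP + (1 - Y) %*% log1mP
}

# posterior node weights (n x Q) and the marginal log-likelihood
posterior_weights <- function(ll, weights) {
  lw <- sweep(ll, 2, log(weights), "+")
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  rs <- rowSums(w)
  list(post = w / rs, loglik = sum(log(rs) + mx))
}

# per-item M-step: Newton maximization of the expected complete-data
# log-likelihood sum_q [ r_q log P_q + (n_q - r_q) log(1 - P_q) ]
mstep_item <- function(a, b, r_q, n_q, nodes, max_iter = 30L) {
  obj <- function(a, b) {
    eta <- a * (nodes - b)
    sum(r_q * stats::plogis(eta, log.p = TRUE) +
          (n_q - r_q) * stats::plogis(-eta, log.p = TRUE))
  }
  f0 <- obj(a, b)
  for (it in seq_len(max_iter)) {
    t_b <- nodes - b
    P <- stats::plogis(a * t_b)
    W <- n_q * P * (1 - P)
    e <- r_q - n_q * P
    g <- c(sum(e * t_b), -a * sum(e))
    H <- matrix(c(-sum(W * t_b^2), a * sum(W * t_b) - sum(e),
                  a * sum(W * t_b) - sum(e), -a^2 * sum(W)), 2, 2)
    step <- tryCatch(solve(H, -g), error = function(e) g * 0.1)
    # damped Newton: halve until the objective does not decrease
    lam <- 1
    repeat {
      a1 <- min(max(a + lam * step[1], 0.01), 15)
      b1 <- min(max(b + lam * step[2], -8), 8)
      f1 <- obj(a1, b1)
      if (f1 >= f0 - 1e-12 || lam < 1e-4) break
      lam <- lam / 2
    }
    if (abs(a1 - a) < 1e-9 && abs(b1 - b) < 1e-9) {
      a <- a1; b <- b1; f0 <- f1
      break
    }
    a <- a1; b <- b1; f0 <- f1
  }
  c(a = a, b = b)
}

#' Fit the 2PL model by marginal maximum likelihood (EM)
#'
#' Estimates item discriminations and difficulties by maximizing the marginal
#' likelihood, integrating ability out against a fixed N(0, 1) prior with
#' Gauss-Hermite quadrature (the prior identifies the ability metric; no
#' post-hoc rescaling is applied). The E-step computes posterior node weights
#' for every examinee; the M-step runs damped per-item Newton updates on the
#' expected complete-data counts. Abilities are then scored by EAP.
#'
#' @param Y Binary response matrix (no missing cells; every item must show
#'   both response categories).
#' @param n_nodes Number of quadrature nodes.
#' @param tol EM convergence tolerance on the largest absolute parameter
#'   change between cycles.
#' @param max_cycles Maximum EM cycles; non-convergence is returned with
#'   `converged = FALSE` and a warning, not an error.
#' @return An object of class `irt_fit`: `a`, `b`, `theta` and `theta_psd`
#'   (EAP point estimates and posterior SDs), `loglik_trace`, `converged`,
#'   `n_cycles`, the expected node counts `n_q`, expected correct counts
#'   `r_kq`, and the quadrature used.
#' @export
fit_2pl_mml <- function(Y, n_nodes = 41L, tol = 1e-4, max_cycles = 500L) {
  Y <- validate_response_matrix(Y)
  n <- nrow(Y); K <- ncol(Y)
  p_hat <- colMeans(Y)
  deg <- which(p_hat <= 0 | p_hat >= 1)
  if (length(deg))
    stop("item(s) with degenerate observed proportion (all 0 or all 1): ",
         paste(colnames(Y)[deg], collapse = ", "))
  if (n < 200)
    warning("n = ", n, " examinees; 2PL MML estimates may be unstable")
  quad <- gh_quadrature(n_nodes)
  a <- rep(1, K)
  b <- -stats::qlogis(p_hat)
  Ymat <- matrix(as.numeric(Y), n, K)
  loglik_trace <- numeric(0)
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    ll <- pattern_loglik(Ymat, a, b, quad$nodes)
    es <- posterior_weights(ll, quad$weights)
    loglik_trace <- c(loglik_trace, es$loglik)
    n_q <- colSums(es$post)
    r_kq <- crossprod(Ymat, es$post)          # K x Q expected correct counts
    new <- vapply(seq_len(K), function(k)
      mstep_item(a[k], b[k], r_kq[k, ], n_q, quad$nodes), numeric(2))
    delta <- max(abs(new[1, ] - a), abs(new[2, ] - b))
    a <- new[1, ]; b <- new[2, ]
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_cycles, " cycles")
  # final E-step quantities at the converged parameters
  ll <- pattern_loglik(Ymat, a, b, quad$nodes)
  es <- posterior_weights(ll, quad$weights)
  eap <- eap_from_posterior(es$post, quad$nodes)
  structure(list(
    a = stats::setNames(a, colnames(Y)),
    b = stats::setNames(b, colnames(Y)),
    theta = eap$theta, theta_psd = eap$psd,
    loglik = es$loglik, loglik_trace = loglik_trace,
    converged = converged, n_cycles = length(loglik_trace),
    n_q = colSums(es$post), r_kq = crossprod(Ymat, es$post),
    quad = quad, n = n, K = K, p_hat = p_hat
  ), class = "irt_fit")
}

#' @export
print.irt_fit <- function(x, ...) {
  cat("2PL MML-EM fit: n =", x$n, ", K =", x$K,
      if (x$converged) "(converged" else "(NOT converged",
      "in", x$n_cycles, "cycles)\n")
  cat("  log-likelihood", format(x$loglik, digits = 8), "\n")
  print(data.frame(a = round(x$a, 3), b = round(x$b, 3)))
  invisible(x)
}

eap_from_posterior <- function(post, nodes) {
  theta <- drop(post %*% nodes)
  second <- drop(post %*% nodes^2)
  list(theta = theta, psd = sqrt(pmax(second - theta^2, 0)))
}

#' EAP ability scores for response patterns
#'
#' Expected-a-posteriori ability: the posterior mean of theta given a
#' response pattern under a N(0, 1) prior, computed on a quadrature grid.
#' Finite for every pattern, including all-correct and all-incorrect.
#'
#' @param Y Binary response matrix (or a single pattern vector).
#' @param a,b Item parameter vectors.
#' @param quad Quadrature from [gh_quadrature()].
#' @return A list with `theta` (posterior means) and `psd` (posterior SDs).
#' @export
eap_score <- function(Y, a, b, quad = gh_quadrature()) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  Y <- matrix(as.numeric(Y), nrow(Y), ncol(Y))
  stopifnot(ncol(Y) == length(a), length(a) == length(b))
  ll <- pattern_loglik(Y, a, b, quad$nodes)
  es <- posterior_weights(ll, quad$weights)
  eap_from_posterior(es$post, quad$nodes)
}

#' Asymptotic standard errors of 2PL item parameters
#'
#' Per-item expected Fisher information accumulated over the posterior node
#' weights of the fitted model:
#' `I(psi_k) = sum_q N_q P_kq (1 - P_kq) [ (t_q - b_k)^2, -a_k (t_q - b_k);
#' -a_k (t_q - b_k), a_k^2 ]` with `N_q` the expected number of examinees at
#' node q. Standard errors are the square roots of the diagonal of the
#' inverse. Cross-item covariance is ignored (block-diagonal per item).
#'
#' @param fit An `irt_fit` from [fit_2pl_mml()].
#' @return A data.frame with per-item `se_a` and `se_b`.
#' @export
asymptotic_se <- function(fit) {
  stopifnot(inherits(fit, "irt_fit"))
  nodes <- fit$quad$nodes
  K <- fit$K
  se <- vapply(seq_len(K), function(k) {
    t_b <- nodes - fit$b[k]
    P <- stats::plogis(fit$a[k] * t_b)
    W <- fit$n_q * P * (1 - P)
    info <- matrix(c(sum(W * t_b^2), -fit$a[k] * sum(W * t_b),
                     -fit$a[k] * sum(W * t_b), fit$a[k]^2 * sum(W)), 2, 2)
    inv <- tryCatch(solve(info), error = function(e)
      stop("singular information matrix for item ", names(fit$a)[k]))
    sqrt(diag(inv))
  }, numeric(2))
  data.frame(item = names(fit$a), se_a = se[1, ], se_b = se[2, ],
             row.names = NULL)
}

#' Infit and Outfit mean-square fit statistics
#'
#' Standardized residuals `z_ik = (Y_ik - P_ik) / sqrt(P_ik (1 - P_ik))` are
#' computed at plug-in abilities (EAP scores by convention). Infit is the
#' information-weighted mean square `sum_i W_ik z_ik^2 / sum_i W_ik` with
#' `W_ik = P_ik (1 - P_ik)`; Outfit is the unweighted mean `mean_i z_ik^2`.
#' Values in `[0.7, 1.3]` indicate adequate fit; values below 0.5 indicate
#' severe under-dispersion (overly deterministic responses). Probabilities
#' are clamped to `[1e-10, 1 - 1e-10]` before residuals are formed.
#'
#' @param Y Binary response matrix.
#' @param a,b Item parameters.
#' @param theta Ability estimates (length `nrow(Y)`).
#' @return A data.frame with per-item `infit`, `outfit`, and a `flag` column
#'   (`""`, `"misfit"`, or `"severe under-dispersion"`).
#' @export
infit_outfit <- function(Y, a, b, theta) {
  Y <- validate_response_matrix(Y)
  stopifnot(length(theta) == nrow(Y), length(a) == ncol(Y))
  P <- stats::plogis(outer(theta, b, "-") %*% diag(a, length(a), length(a)))
  P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
  W <- P * (1 - P)
  R2 <- (Y - P)^2
  infit <- colSums(R2) / colSums(W)
  outfit <- colMeans(R2 / W)
  flag <- ifelse(outfit < 0.5 | infit < 0.5, "severe under-dispersion",
                 ifelse(infit < 0.7 | infit > 1.3 |
                          outfit < 0.7 | outfit > 1.3, "misfit", ""))
  data.frame(item = colnames(Y), infit = infit, outfit = outfit,
             flag = flag, row.names = NULL)
}
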