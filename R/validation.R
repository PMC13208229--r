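#' Total-score distribution summary
#'
#' Moments of the row-sum (total score) distribution: mean, SD (n-1
#' denominator), and population-moment skewness and EXCESS kurtosis. With a
#' degenerate (constant) score distribution the shape statistics are
#' undefined and reported as `NA`.
#'
#' @param Y Binary response matrix (n >= 2).
#' @return A one-row data.frame: `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
score_distribution_summary <- function(Y) {
  Y <- validate_response_matrix(Y)
  stopifnot(nrow(Y) >= 2)
  s <- rowSums(Y)
  m <- mean(s)
  dev <- s - m
  m2 <- mean(dev^2)
  if (m2 == 0)
    return(data.frame(mean = m, sd = 0, skewness = NA_real_,
                      kurtosis = NA_real_))
  data.frame(mean = m, sd = stats::sd(s),
             skewness = mean(dev^3) / m2^1.5,
             kurtosis = mean(dev^4) / m2^2 - 3)
}

#' Marginal-probability fidelity metrics from marginal vectors
#'
#' Compares per-item proportions of correct responses between a real and a
#' synthetic dataset: absolute and relative per-item deviations, their mean
#' absolute deviation `MAD = mean_k |p_real_k - p_syn_k|`, mean relative
#' error (percent), and the Pearson correlation of the two vectors.
#'
#' @param p_real,p_syn Marginal probability vectors of equal length.
#' @return A list with `table` (per item), `mad`, `mean_relative_pct`,
#'   `max_abs_diff`, and `r`.
#' @export
marginal_metrics <- function(p_real, p_syn) {
  stopifnot(length(p_real) == length(p_syn))
  abs_diff <- abs(p_real - p_syn)
  rel <- abs_diff / p_real * 100
  list(table = data.frame(item = seq_along(p_real), p_real = p_real,
                          p_syn = p_syn, abs_diff = abs_diff,
                          relative_pct = rel),
       mad = mean(abs_diff),
       mean_relative_pct = mean(rel),
       max_abs_diff = max(abs_diff),
       r = safe_cor(p_real, p_syn))
}

safe_cor <- function(x, y) {
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y)
}

#' Marginal facet: item proportions with bootstrap intervals
#'
#' [marginal_metrics()] on the column means of two response matrices, plus
#' percentile bootstrap 95% confidence intervals on each real marginal from
#' resampling rows of the real data with replacement.
#'
#' @param Y_real,Y_syn Binary response matrices with the same items.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @return The [marginal_metrics()] list with `ci_lower`/`ci_upper` columns
#'   added to `table` and a `within_ci` count.
#' @export
marginal_facet <- function(Y_real, Y_syn, n_boot = 1000L, seed = 1L) {
  Y_real <- validate_response_matrix(Y_real)
  Y_syn <- validate_response_matrix(Y_syn)
  if (ncol(Y_real) != ncol(Y_syn)) stop("item count mismatch")
  out <- marginal_metrics(colMeans(Y_real), colMeans(Y_syn))
  n <- nrow(Y_real)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i)
      colMeans(Y_real[sample.int(n, n, replace = TRUE), , drop = FALSE]),
      numeric(ncol(Y_real)))
  })
  ci <- apply(boots, 1, stats::quantile, probs = c(0.025, 0.975))
  out$table$ci_lower <- ci[1, ]
  out$table$ci_upper <- ci[2, ]
  out$within_ci <- sum(out$table$p_syn >= ci[1, ] &
                         out$table$p_syn <= ci[2, ])
  out
}

#' Dependence facet: RMSR of inter-item correlation matrices
#'
#' Root mean square residual over the `K (K - 1) / 2` unique item pairs of
#' the difference between the real and synthetic Pearson correlation
#' matrices. Values below 0.05 are conventionally read as good structural
#' fit.
#'
#' @param Y_real,Y_syn Binary response matrices with the same items.
#' @return The scalar RMSR.
#' @export
dependence_facet <- function(Y_real, Y_syn) {
  Y_real <- validate_response_matrix(Y_real)
  Y_syn <- validate_response_matrix(Y_syn)
  K <- ncol(Y_real)
  if (K != ncol(Y_syn)) stop("item count mismatch")
  if (K < 2) stop("need at least two items")
  for (nm in list(list(Y_real, "real"), list(Y_syn, "synthetic"))) {
    cst <- which(apply(nm[[1]], 2, stats::sd) == 0)
    if (length(cst))
      stop("constant column(s) in ", nm[[2]], " data: ",
           paste(colnames(nm[[1]])[cst], collapse = ", "))
  }
  dr <- stats::cor(Y_real) - stats::cor(Y_syn)
  sqrt(sum(dr[upper.tri(dr)]^2) / (K * (K - 1) / 2))
}

#' Psychometric facet: parameter recovery and information profiles
#'
#' For discrimination and difficulty separately: Pearson correlation, mean
#' absolute deviation `MAD = mean |psi_real - psi_syn|`, and root mean
#' squared deviation `RMSD = sqrt(mean (psi_real - psi_syn)^2)` between the
#' real-data and synthetic-data estimates. Test information and conditional
#' standard error profiles are evaluated on the ability grid for both
#' parameter sets and compared by Pearson correlation.
#'
#' @param a_real,b_real,a_syn,b_syn Item parameter vectors (equal length).
#' @param grid Ability grid (default [ability_grid()]).
#' @return A list with components `a` and `b` (each `r`, `mad`, `rmsd`),
#'   `r_tif`, `r_csem`, and the two information profiles.
#' @export
psychometric_facet <- function(a_real, b_real, a_syn, b_syn,
                               grid = ability_grid()) {
  stopifnot(length(a_real) == length(b_real),
            length(a_real) == length(a_syn),
            length(a_syn) == length(b_syn))
  pm <- function(x, y) list(r = safe_cor(x, y), mad = mean(abs(x - y)),
                            rmsd = sqrt(mean((x - y)^2)))
  prof_real <- test_information_and_csem(a_real, b_real, grid)
  prof_syn <- test_information_and_csem(a_syn, b_syn, grid)
  list(a = pm(a_real, a_syn), b = pm(b_real, b_syn),
       r_tif = safe_cor(prof_real$tif, prof_syn$tif),
       r_csem = safe_cor(prof_real$csem, prof_syn$csem),
       profile_real = prof_real, profile_syn = prof_syn)
}

#' Monte-Carlo standard errors from replicated estimates
#'
#' The MCSE of a parameter is the sample standard deviation (n-1
#' denominator) of its estimates across replications.
#'
#' @param estimates M x K matrix of per-replication estimates (M >= 2).
#' @return Numeric vector of length K.
#' @export
mcse <- function(estimates) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 2) stop("MCSE requires at least 2 replications")
  apply(estimates, 2, stats::sd)
}

#' Inferential-precision facet: MCSE versus asymptotic SE
#'
#' Generates `M` independent synthetic datasets from the model, refits the
#' 2PL on each, and summarizes the sampling variability of the item
#' parameter estimates as Monte-Carlo standard errors, compared against the
#' asymptotic standard errors of a reference fit (typically the real
#' training data). The ratio MCSE/ASE near 1 indicates that synthetic data
#' reproduce the inferential precision of the real data; above 1,
#' conservative standard errors; below 1, over-smoothed variability.
#' Non-convergent replications are excluded and counted; if more than 10%
#' are excluded the report is flagged.
#'
#' @param model An `nnc_model`.
#' @param reference An `irt_fit` on the reference (real) data.
#' @param M Number of replications (>= 2).
#' @param m Examinees per replication (default: the model's training n).
#' @param master_seed Seed for the replication child seeds.
#' @param n_nodes Quadrature size for the refits.
#' @return A list with the per-item table (`se_mc_a`, `se_asym_a`,
#'   `ratio_a`, and likewise for `b`), `mean_se_mc_a`, `mean_se_asym_a`,
#'   `mean_ratio_a`, the `b` analogues, `n_excluded`, and `flagged`.
#' @export
mc_precision <- function(model, reference, M, m = model$n_train,
                         master_seed = 1L, n_nodes = 41L) {
  stopifnot(M >= 2, inherits(reference, "irt_fit"))
  seeds <- spawn_seeds(master_seed, M)
  est_a <- matrix(NA_real_, M, reference$K)
  est_b <- matrix(NA_real_, M, reference$K)
  for (r in seq_len(M)) {
    Yr <- nnc_generate(model, m, seed = seeds[r])
    fit <- tryCatch(
      suppressWarnings(fit_2pl_mml(Yr, n_nodes = n_nodes)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      est_a[r, ] <- fit$a
      est_b[r, ] <- fit$b
    }
  }
  ok <- stats::complete.cases(est_a)
  n_excl <- sum(!ok)
  if (sum(ok) < 2) stop("fewer than 2 convergent replications")
  se_mc_a <- mcse(est_a[ok, , drop = FALSE])
  se_mc_b <- mcse(est_b[ok, , drop = FALSE])
  ase <- asymptotic_se(reference)
  tab <- data.frame(item = ase$item,
                    se_asym_a = ase$se_a, se_mc_a = se_mc_a,
                    ratio_a = se_mc_a / ase$se_a,
                    se_asym_b = ase$se_b, se_mc_b = se_mc_b,
                    ratio_b = se_mc_b / ase$se_b)
  list(table = tab,
       mean_se_mc_a = mean(se_mc_a), mean_se_asym_a = mean(ase$se_a),
       mean_ratio_a = mean(tab$ratio_a),
       mean_se_mc_b = mean(se_mc_b), mean_se_asym_b = mean(ase$se_b),
       mean_ratio_b = mean(tab$ratio_b),
       mean_a = colMeans(est_a[ok, , drop = FALSE]),
       mean_b = colMeans(est_b[ok, , drop = FALSE]),
       n_excluded = n_excl, M = M,
       flagged = n_excl > 0.1 * M)
}

#' Stability facet: cross-seed reproducibility of the pipeline
#'
#' Retrains the complete model from scratch once per seed, generates one
#' synthetic dataset per run, and records the primary fidelity metrics
#' (correlations of recovered discrimination and difficulty against the
#' reference fit, and the marginal MAD). Low across-seed dispersion
#' indicates that the generator converges to an equivalent solution
#' regardless of initialization.
#'
#' @param Y_train,Y_val Binary partitions used for every retraining.
#' @param reference An `irt_fit` on the real training data.
#' @param config An [nnc_config()].
#' @param seeds Integer vector of run seeds (>= 2), default
#'   `c(101, 202, 303, 404, 505)`.
#' @param n_nodes Quadrature size for the synthetic refits.
#' @return A list with `table` (per seed: `r_a`, `r_b`, `mad_marginal`) and
#'   `summary` (mean and n-1 SD per metric).
#' @export
stability_facet <- function(Y_train, Y_val, reference,
                            config = nnc_config(),
                            seeds = c(101L, 202L, 303L, 404L, 505L),
                            n_nodes = 41L) {
  stopifnot(length(seeds) >= 2)
  rows <- lapply(seeds, function(s) {
    res <- tryCatch({
      model <- nnc_train(Y_train, Y_val, config, seed = s)
      Ys <- nnc_generate(model, model$n_train, seed = s)
      fit <- suppressWarnings(fit_2pl_mml(Ys, n_nodes = n_nodes))
      data.frame(seed = s,
                 r_a = safe_cor(reference$a, fit$a),
                 r_b = safe_cor(reference$b, fit$b),
                 mad_marginal = mean(abs(colMeans(Y_train) - colMeans(Ys))))
    }, error = function(e) {
      warning("stability run for seed ", s, " failed: ",
              conditionMessage(e))
      data.frame(seed = s, r_a = NA_real_, r_b = NA_real_,
                 mad_marginal = NA_real_)
    })
    res
  })
  tab <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("r_a", "r_b", "mad_marginal"),
    mean = c(mean(tab$r_a, na.rm = TRUE), mean(tab$r_b, na.rm = TRUE),
             mean(tab$mad_marginal, na.rm = TRUE)),
    sd = c(stats::sd(tab$r_a, na.rm = TRUE),
           stats::sd(tab$r_b, na.rm = TRUE),
           stats::sd(tab$mad_marginal, na.rm = TRUE)))
  list(table = tab, summary = summ)
}

#' Sensitivity of fidelity metrics to latent dimension and bandwidth
#'
#' For every latent dimension in `d_grid` the autoencoder is retrained once;
#' for every bandwidth in `h_grid` the latent KDE is refitted on the same
#' codes (training is bandwidth-free, so no retrain is needed) and `M`
#' synthetic replications are generated and refitted. Each configuration row
#' reports the mean `r_a`, `r_b`, marginal MAD, and dependence RMSR across
#' replications.
#'
#' @param Y_train,Y_val Binary partitions.
#' @param reference An `irt_fit` on the real training data.
#' @param d_grid,h_grid Candidate latent dimensions and bandwidths.
#' @param M Replications per configuration (default 50).
#' @param config Base [nnc_config()] (its `latent_dim`/`kde_bandwidth` are
#'   overridden by the grids).
#' @param master_seed Seed governing training and generation.
#' @param n_nodes Quadrature size for refits.
#' @return A data.frame with one row per (parameter, value) configuration:
#'   `parameter`, `value`, `r_a`, `r_b`, `mad_marginal`, `rmsr`.
#' @export
sensitivity_driver <- function(Y_train, Y_val, reference,
                               d_grid = c(10L, 20L, 30L, 50L),
                               h_grid = c(0.1, 0.2, 0.3, 0.5),
                               M = 50L, config = nnc_config(),
                               master_seed = 1L, n_nodes = 41L) {
  stopifnot(length(d_grid) >= 1, length(h_grid) >= 1)
  p_train <- colMeans(Y_train)
  eval_model <- function(model, M, seed0) {
    seeds <- spawn_seeds(seed0, M)
    mets <- vapply(seeds, function(s) {
      Ys <- nnc_generate(model, model$n_train, seed = s)
      fit <- tryCatch(suppressWarnings(fit_2pl_mml(Ys, n_nodes = n_nodes)),
                      error = function(e) NULL)
      if (is.null(fit)) return(rep(NA_real_, 4))
      c(safe_cor(reference$a, fit$a), safe_cor(reference$b, fit$b),
        mean(abs(p_train - colMeans(Ys))),
        dependence_facet(Y_train, Ys))
    }, numeric(4))
    rowMeans(mets, na.rm = TRUE)
  }
  rows <- list()
  seeds_d <- spawn_seeds(master_seed, length(d_grid) + 1L)
  for (i in seq_along(d_grid)) {
    cfg <- config; cfg$latent_dim <- as.integer(d_grid[i])
    model <- nnc_train(Y_train, Y_val, cfg, seed = seeds_d[i])
    m <- eval_model(model, M, seeds_d[i])
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "latent_dim", value = d_grid[i],
      r_a = m[1], r_b = m[2], mad_marginal = m[3], rmsr = m[4])
    if (d_grid[i] == config$latent_dim) base_model <- model
  }
  if (!exists("base_model", inherits = FALSE)) {
    cfg <- config
    base_model <- nnc_train(Y_train, Y_val, cfg,
                            seed = seeds_d[length(seeds_d)])
  }
  for (h in h_grid) {
    model_h <- base_model
    model_h$kde <- fit_kde(base_model$kde$codes, h = h)
    m <- eval_model(model_h, M, seeds_d[length(seeds_d)])
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "bandwidth", value = h,
      r_a = m[1], r_b = m[2], mad_marginal = m[3], rmsr = m[4])
  }
  do.call(rbind, rows)
}

#' Assemble and optionally write the full validation report
#'
#' Bundles the data-level, psychometric, and fit-statistic comparisons of a
#' single synthetic dataset against the real training data into one report
#' (JSON-serializable, with a schema version field). The precision and
#' stability facets are computed by [mc_precision()] and
#' [stability_facet()] and can be attached by the caller.
#'
#' @param Y_real,Y_syn Binary response matrices.
#' @param fit_real,fit_syn `irt_fit` objects for the two datasets (fitted if
#'   omitted).
#' @param n_boot Bootstrap resamples for the marginal facet.
#' @param seed Seed for the bootstrap.
#' @param path Optional path; when given the report is written as JSON.
#' @return A list of class `nnc_report`.
#' @export
validate_synthetic <- function(Y_real, Y_syn, fit_real = NULL,
                               fit_syn = NULL, n_boot = 1000L, seed = 1L,
                               path = NULL) {
  Y_real <- validate_response_matrix(Y_real)
  Y_syn <- validate_response_matrix(Y_syn)
  if (is.null(fit_real)) fit_real <- suppressWarnings(fit_2pl_mml(Y_real))
  if (is.null(fit_syn)) fit_syn <- suppressWarnings(fit_2pl_mml(Y_syn))
  psych <- psychometric_facet(fit_real$a, fit_real$b, fit_syn$a, fit_syn$b)
  fit_stats_real <- infit_outfit(Y_real, fit_real$a, fit_real$b,
                                 fit_real$theta)
  fit_stats_syn <- infit_outfit(Y_syn, fit_syn$a, fit_syn$b, fit_syn$theta)
  report <- structure(list(
    schema_version = "1.0",
    scores = list(real = score_distribution_summary(Y_real),
                  synthetic = score_distribution_summary(Y_syn)),
    marginal = marginal_facet(Y_real, Y_syn, n_boot = n_boot, seed = seed),
    rmsr = dependence_facet(Y_real, Y_syn),
    psychometric = psych[c("a", "b", "r_tif", "r_csem")],
    fit_statistics = list(real = fit_stats_real, synthetic = fit_stats_syn,
                          mean_abs_infit_diff =
                            mean(abs(fit_stats_real$infit -
                                       fit_stats_syn$infit))),
    params = data.frame(item = names(fit_real$a),
                        a_real = unname(fit_real$a),
                        a_syn = unname(fit_syn$a),
                        b_real = unname(fit_real$b),
                        b_syn = unname(fit_syn$b))
  ), class = "nnc_report")
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.nnc_report <- function(x, ...) {
  cat("Synthetic-data validation report (schema", x$schema_version, ")\n")
  cat(sprintf("  marginal: MAD %.3f | mean rel %% %.3f | r %.3f\n",
              x$marginal$mad, x$marginal$mean_relative_pct, x$marginal$r))
  cat(sprintf("  dependence RMSR %.3f\n", x$rmsr))
  cat(sprintf("  a: r %.3f MAD %.3f RMSD %.3f | b: r %.3f MAD %.3f RMSD %.3f\n",
              x$psychometric$a$r, x$psychometric$a$mad,
              x$psychometric$a$rmsd, x$psychometric$b$r,
              x$psychometric$b$mad, x$psychometric$b$rmsd))
  cat(sprintf("  r(TIF) %.3f | r(CSEM) %.3f | mean |Infit diff| %.4f\n",
              x$psychometric$r_tif, x$psychometric$r_csem,
              x$fit_statistics$mean_abs_infit_diff))
  invisible(x)
}
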