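# Shared fixtures, built lazily and cached for the whole test run.
# The main fixture emulates the reference study conditions: a 20-item
# unidimensional 2PL assessment with ~5000 examinees, stratified into
# 64/16/20 train/validation/test partitions, with the copula model trained
# on the training rows (n ~ 3244).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fixture_study <- function() {
  fixture("study", function() {
    design <- sim_design(5069, 20, seed = 11)
    sim <- simulate_2pl(design)
    parts <- stratified_partition(sim$Y, seed = 5)
    list(sim = sim, parts = parts)
  })
}

fixture_fit_real <- function() {
  fixture("fit_real", function() {
    suppressWarnings(fit_2pl_mml(fixture_study()$parts$train))
  })
}

fixture_model <- function() {
  fixture("model", function() {
    st <- fixture_study()
    nnc_train(st$parts$train, st$parts$validation, nnc_config(), seed = 42)
  })
}

fixture_synth <- function() {
  fixture("synth", function() {
    nnc_generate(fixture_model(), seed = 42)
  })
}

fixture_fit_synth <- function() {
  fixture("fit_synth", function() {
    suppressWarnings(fit_2pl_mml(fixture_synth()))
  })
}

# medium-scale parameter-recovery fixture shared between the estimation unit
# tests and the recovery acceptance check
fixture_recovery <- function() {
  fixture("recovery", function() {
    design <- sim_design(5000, 20, seed = 7)
    sim <- simulate_2pl(design)
    fit <- suppressWarnings(fit_2pl_mml(sim$Y))
    list(sim = sim, fit = fit)
  })
}

benchmark_csv <- function(which) {
  utils::read.csv(system.file("extdata",
                              paste0("numeracy_benchmark_", which, ".csv"),
                              package = "nncopula"))
}

# tiny deterministic pseudo-uniform fixture for network unit tests
tiny_uniform_fixture <- function(n = 300, K = 8, seed = 3) {
  design <- sim_design(n, K, seed = seed)
  sim <- simulate_2pl(design)
  p <- colMeans(sim$Y)
  p <- pmin(pmax(p, 0.05), 0.95)
  randomized_pit(sim$Y, p, seed = seed)
}
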