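# Shared fixtures: everything is generated in code at test time.

# Small trial for fast fits.
small_trial <- function(n = 20, seed = 1, truth = trial_truth(),
                        visits = twice_weekly_schedule(70), ...) {
  generate_trial(
    trial_design(n_patients = n, visit_schedule = visits, ...),
    truth = truth, seed = seed
  )
}

# Short-chain fit for unit tests (not for inference quality).
quick_fit <- function(data, family, seed = 1, warmup = 300, iter = 300,
                      chains = 2, ...) {
  suppressWarnings(
    wound_fit(data, family, chains = chains, warmup = warmup, iter = iter,
              seed = seed, ...)
  )
}

# Hand-built wound_fit with draws supplied directly: used to test estimand
# algebra against closed forms without running MCMC.
fake_fit <- function(draws, family, t_max = 100, basis = NULL) {
  k <- (ncol(draws) - 3L) / 2L
  stopifnot(all(c("mu", "tau", "omega") %in% names(draws)))
  draws <- tibble::as_tibble(draws)
  draws <- dplyr::bind_cols(
    tibble::tibble(.chain = 1L, .iteration = seq_len(nrow(draws))), draws)
  structure(
    list(draws = draws, family = family, t_max = t_max, basis = basis,
         meta = list(n_obs = 0L, n_patients = 0L)),
    class = "wound_fit"
  )
}

# Draws tibble helper: rho columns named rho0_1.., rho1_1..
make_draws <- function(mu, tau, omega, rho0, rho1) {
  rho0 <- matrix(rho0, nrow = length(mu))
  rho1 <- matrix(rho1, nrow = length(mu))
  d <- tibble::tibble(mu = mu, tau = tau, omega = omega)
  for (j in seq_len(ncol(rho0))) d[[paste0("rho0_", j)]] <- rho0[, j]
  for (j in seq_len(ncol(rho1))) d[[paste0("rho1_", j)]] <- rho1[, j]
  d
}

all_families <- function() healing_families()$family

# Valid example parameters per family (healing-shaped, f > 0 on [0, 70]).
example_rho <- function(family) {
  switch(family,
    exponential = 0.03, gompertz = 0.02, linear = -0.012,
    quadratic = c(-0.016, 0.0001), square_root = c(-0.004, -0.07),
    wendland0 = 2, wendland1 = 2,
    semiparametric = rep(0.05, 8),
    log_linear = -0.012, log_quadratic = c(-0.016, 0.0001),
    log_square_root = c(-0.004, -0.07)
  )
}

example_hf <- function(family, t_max = 100) {
  basis <- if (family == "semiparametric") spline_basis(c(0, 70)) else NULL
  healing_function(family, example_rho(family), t_max = t_max, basis = basis)
}
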