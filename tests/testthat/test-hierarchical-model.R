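# The hierarchical log-linear model: pointwise likelihood, the mean-one
# error convention and the simulator's marginal moments.

toy_spec <- function(...) {
  args <- modifyList(
    list(family = "linear", mu = log(4), tau = 0.5, omega = 0.5,
         rho0 = -0.01, rho1 = -0.01),
    list(...)
  )
  do.call(model_spec, args)
}

test_that("beta0 reconciles the mean-one error convention", {
  spec <- toy_spec(omega = 0.4)
  expect_equal(beta0(spec), spec$mu - 0.4^2 / 2)
})

test_that("pointwise log-likelihood matches a direct normal density oracle", {
  spec <- toy_spec()
  data <- tibble::tibble(
    patient_id = c("a", "a", "b"), arm = c(0L, 0L, 1L),
    day = c(0, 10, 20), area_cm2 = c(4.1, 3.0, 2.2), method = "m"
  )
  alpha <- c(a = 0.2, b = -0.1)
  ll <- log_lik_pointwise(spec, alpha, data)
  # independent oracle: mean built term by term from the model statement
  f <- 1 + (-0.01) * data$day
  m <- (log(4) - 0.5^2 / 2) + alpha[c("a", "a", "b")] + log(f)
  oracle <- dnorm(log(data$area_cm2), unname(m), 0.5, log = TRUE)
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("zero residual gives the normal density mode", {
  spec <- toy_spec(omega = 0.5)
  # f(0) = 1, alpha = 0, so mean = beta0; choose area = exp(beta0)
  data <- tibble::tibble(patient_id = "a", arm = 0L, day = 0,
                         area_cm2 = exp(beta0(spec)), method = "m")
  expect_equal(log_lik_pointwise(spec, c(a = 0), data),
               -log(0.5 * sqrt(2 * pi)))
})

test_that("f <= 0 at an observed time yields -Inf, not an error", {
  spec <- toy_spec(rho0 = -0.1)           # f(20) = -1
  data <- tibble::tibble(patient_id = c("a", "a"), arm = 0L, day = c(2, 20),
                         area_cm2 = c(4, 4), method = "m")
  ll <- log_lik_pointwise(spec, c(a = 0), data)
  expect_true(is.finite(ll[1]))
  expect_identical(ll[2], -Inf)
})

test_that("left-censored rows contribute the lower-tail probability", {
  spec <- toy_spec()
  data <- tibble::tibble(patient_id = "a", arm = 0L, day = 0,
                         area_cm2 = 0.25, method = "m", censored = TRUE)
  ll <- log_lik_pointwise(spec, c(a = 0), data)
  expect_equal(ll, pnorm(log(0.25), beta0(spec), 0.5, log.p = TRUE))
})

test_that("alpha must cover every patient", {
  spec <- toy_spec()
  data <- tibble::tibble(patient_id = c("a", "b"), arm = 0L, day = 0,
                         area_cm2 = 4, method = "m")
  expect_error(log_lik_pointwise(spec, c(a = 0), data), "cover every patient")
})

test_that("degenerate noise reproduces exp(mu) * f(t) exactly", {
  spec <- toy_spec(tau = 0, omega = 0)
  design <- expand.grid(patient_id = c("a", "b"), arm = NA, day = c(0, 10, 30))
  design$arm <- ifelse(design$patient_id == "a", 0L, 1L)
  sim <- simulate_wounds(spec, design, seed = 3)
  expect_equal(sim$area_cm2, 4 * (1 - 0.01 * sim$day))
})

test_that("multiplicative error is mean-one: closed form and Monte Carlo", {
  # closed form: E exp(N(-w^2/2, w^2)) = exp(-w^2/2 + w^2/2) = 1
  for (w in c(0.1, 0.5)) {
    expect_equal(exp(-w^2 / 2 + w^2 / 2), 1)
    set.seed(99)
    u <- exp(rnorm(2e5, -w^2 / 2, w))
    se <- sd(u) / sqrt(length(u))
    expect_lt(abs(mean(u) - 1), 3 * se)
  }
})

test_that("marginal mean area is exp(mu + tau^2/2) f(t)", {
  spec <- toy_spec(tau = 0.4, omega = 0.3)
  n <- 4e4
  design <- tibble::tibble(patient_id = sprintf("p%05d", 1:n), arm = 0L,
                           day = 30)
  sim <- simulate_wounds(spec, design, seed = 5)
  f30 <- 1 - 0.01 * 30
  expected <- exp(log(4) + 0.4^2 / 2) * f30
  se <- sd(sim$area_cm2) / sqrt(n)
  expect_lt(abs(mean(sim$area_cm2) - expected), 3 * se)
})

test_that("simulation is deterministic given the seed", {
  spec <- toy_spec()
  design <- tibble::tibble(patient_id = rep(c("a", "b"), each = 3),
                           arm = rep(c(0L, 1L), each = 3),
                           day = rep(c(0, 7, 14), 2))
  expect_identical(simulate_wounds(spec, design, seed = 11),
                   simulate_wounds(spec, design, seed = 11))
  s2 <- simulate_wounds(spec, design, seed = 12)
  expect_false(identical(simulate_wounds(spec, design, seed = 11)$area_cm2,
                         s2$area_cm2))
})

test_that("generating spec beats a rho-perturbed spec in total log-likelihood", {
  # perturbation: rho shifted by 2 prior sd (prior sd 1)
  spec <- toy_spec(family = "exponential", rho0 = 0.03, rho1 = 0.03,
                   omega = 0.3)
  shifted <- toy_spec(family = "exponential", rho0 = 2.03, rho1 = 2.03,
                      omega = 0.3)
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    design <- tidyr::crossing(patient_id = sprintf("p%02d", 1:50),
                              day = twice_weekly_schedule(70)) %>%
      dplyr::mutate(arm = as.integer(substr(patient_id, 2, 3) %in%
                                       sprintf("%02d", 1:25)))
    sim <- simulate_wounds(spec, design, seed = 100 + r)
    w0 <- attr(sim, "w0")
    alpha <- w0 - spec$mu
    ll_true <- sum(log_lik_pointwise(spec, alpha, sim))
    ll_shift <- sum(log_lik_pointwise(shifted, alpha, sim))
    if (ll_true > ll_shift) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.95)
})
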