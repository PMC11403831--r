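# Treatment-effect estimands: closed forms against hand algebra and a
# brute-force simulation oracle, plus the comparator estimator.

test_that("identical arms give exactly zero effect curves", {
  set.seed(8)
  d <- make_draws(mu = rnorm(40, 1.5, 0.2), tau = runif(40, 0.2, 0.6),
                  omega = runif(40, 0.2, 0.4),
                  rho0 = cbind(runif(40, -0.006, -0.002), runif(40, -0.09, -0.05)),
                  rho1 = cbind(NA, NA))
  d$rho1_1 <- d$rho0_1; d$rho1_2 <- d$rho0_2
  fit <- fake_fit(d, "square_root")
  grid <- seq(0, 70, by = 7)
  expect_true(all(abs(delta1(fit, grid)$mean) < 1e-12))
  expect_true(all(abs(delta2(fit, grid)$mean) < 1e-12))
  expect_true(all(abs(rate_difference(fit, seq(1, 70, 7))$mean) < 1e-12))
  ph <- proportion_healed(fit, grid)
  expect_true(all(abs(ph$mean[ph$arm == "difference"]) < 1e-12))
})

test_that("single-draw delta1 matches hand algebra", {
  # mu = 1, tau = 0.5, omega = 0.5; linear arms with f1(1) = 0.8, f0(1) = 0.9
  d <- make_draws(mu = 1, tau = 0.5, omega = 0.5, rho0 = -0.1, rho1 = -0.2)
  fit <- fake_fit(d, "linear")
  ec <- delta1(fit, t_grid = 1)
  expect_equal(ec$mean, exp(1.125) * (-0.1), tolerance = 1e-12)
})

test_that("delta2 matches direct arithmetic for exponential arms", {
  d <- make_draws(mu = 1, tau = 0.3, omega = 0.2, rho0 = 0.03, rho1 = 0.05)
  fit <- fake_fit(d, "exponential")
  expect_equal(delta2(fit, 10)$mean, exp(-0.5) - exp(-0.3))
  # normalized log-linear arms are exactly 0 at t = 0
  dl <- make_draws(mu = 1, tau = 0.3, omega = 0.2, rho0 = -0.01, rho1 = -0.03)
  fl <- fake_fit(dl, "log_linear")
  expect_equal(delta2(fl, 0, normalize = TRUE)$mean, 0)
  # unnormalized log-family delta2 at 0 is f1(0) - f0(0) = e - e = 0 too,
  # but at t > 0 normalization changes the value
  expect_false(isTRUE(all.equal(delta2(fl, 20)$mean,
                                delta2(fl, 20, normalize = TRUE)$mean)))
})

test_that("delta1 equals exp(mu + tau^2/2) * delta2 draw by draw", {
  set.seed(12)
  d <- make_draws(mu = rnorm(30, 1.5, 0.3), tau = runif(30, 0, 0.6),
                  omega = runif(30, 0.1, 0.5),
                  rho0 = runif(30, 0.02, 0.04), rho1 = runif(30, 0.02, 0.04))
  fit <- fake_fit(d, "exponential")
  grid <- c(0, 10, 42, 70)
  f1 <- woundcurve:::fit_f_draws(fit, grid, 1)
  f0 <- woundcurve:::fit_f_draws(fit, grid, 0)
  d1 <- exp(d$mu + d$tau^2 / 2) * (f1 - f0)
  # the printed delta1 form exp(beta0 + (tau^2+omega^2)/2)(f1 - f0)
  d1_printed <- exp((d$mu - d$omega^2 / 2) + (d$tau^2 + d$omega^2) / 2) *
    (f1 - f0)
  expect_equal(d1, d1_printed, tolerance = 1e-12)
})

test_that("closed-form delta1 agrees with a brute-force simulation oracle", {
  set.seed(33)
  n_sim <- 2e5
  for (rep in 1:3) {
    mu <- rnorm(1, 1.5, 0.2); tau <- runif(1, 0.2, 0.5)
    omega <- runif(1, 0.2, 0.4)
    r0 <- runif(1, 0.02, 0.04); r1 <- runif(1, 0.01, 0.03)
    t <- runif(1, 10, 60)
    f0 <- exp(-r0 * t); f1 <- exp(-r1 * t)
    closed <- exp(mu + tau^2 / 2) * (f1 - f0)
    sim_arm <- function(f) {
      w <- rnorm(n_sim, mu, tau)
      eps <- rnorm(n_sim, -omega^2 / 2, omega)
      exp(w) * f * exp(eps)
    }
    y1 <- sim_arm(f1); y0 <- sim_arm(f0)
    se <- sqrt(var(y1) / n_sim + var(y0) / n_sim)
    expect_lt(abs((mean(y1) - mean(y0)) - closed), 3 * se)
  }
})

test_that("rate difference: linear arms and the average->instantaneous limit", {
  # exp(mu + tau^2/2) = 4 with tau = 0
  d <- make_draws(mu = log(4), tau = 0, omega = 0.3, rho0 = -0.01,
                  rho1 = -0.02)
  fit <- fake_fit(d, "linear")
  ec <- rate_difference(fit, c(5, 20, 50), mode = "instantaneous")
  expect_equal(ec$mean, rep(4 * (-0.01), 3))
  # smooth family: average rate over [0, T] converges to instantaneous
  de <- make_draws(mu = 1, tau = 0.2, omega = 0.2, rho0 = 0.03, rho1 = 0.05)
  fe <- fake_fit(de, "exponential")
  inst <- rate_difference(fe, 1e-3, mode = "instantaneous")$mean
  avg <- rate_difference(fe, 1e-3, mode = "average")$mean
  expect_equal(avg, inst, tolerance = 1e-3)
  expect_error(rate_difference(fe, c(0, 1)), "t > 0")
})

test_that("proportion healed: boundary convention, limits and monotonicity", {
  # mu = log 4, tau -> 0, f = 0.5 (linear, t = 1), c = 2: boundary, so 0.5
  d <- make_draws(mu = log(4), tau = 0, omega = 0.3, rho0 = -0.5, rho1 = -0.5)
  fit <- fake_fit(d, "linear")
  ph <- proportion_healed(fit, 1, threshold = 2)
  expect_equal(ph$mean[ph$arm == "0"], 0.5)
  # threshold far above any baseline: proportion ~ 1
  d2 <- make_draws(mu = log(4), tau = 0.3, omega = 0.3, rho0 = 0.02,
                   rho1 = 0.02)
  f2 <- fake_fit(d2, "exponential")
  ph2 <- proportion_healed(f2, c(10, 40), threshold = 1000)
  expect_true(all(ph2$mean[ph2$arm != "difference"] > 0.999))
  # non-increasing f => non-decreasing proportion healed over time
  ph3 <- proportion_healed(f2, seq(0, 70, 5), threshold = 1)
  for (a in c("0", "1")) {
    expect_true(all(diff(ph3$mean[ph3$arm == a]) >= -1e-12))
  }
  # compact support: fully healed at t_max
  d4 <- make_draws(mu = log(4), tau = 0.4, omega = 0.3, rho0 = 2, rho1 = 2)
  f4 <- fake_fit(d4, "wendland0", t_max = 100)
  ph4 <- proportion_healed(f4, c(99, 100, 110), threshold = 0.25)
  expect_equal(ph4$mean[ph4$arm == "1"][2:3], c(1, 1))
})

test_that("effect curves are internally ordered (lower <= mean <= upper)", {
  set.seed(77)
  d <- make_draws(mu = rnorm(50, 1.5, 0.2), tau = runif(50, 0.1, 0.5),
                  omega = runif(50, 0.1, 0.4),
                  rho0 = runif(50, 0.02, 0.05), rho1 = runif(50, 0.01, 0.04))
  fit <- fake_fit(d, "exponential")
  for (ec in list(delta1(fit), delta2(fit), rate_difference(fit),
                  proportion_healed(fit))) {
    expect_true(all(ec$lower <= ec$mean + 1e-12))
    expect_true(all(ec$mean <= ec$upper + 1e-12))
  }
})

test_that("nonparametric difference matches a hand Welch computation", {
  data <- tibble::tibble(
    patient_id = c("a", "b", "c", "d", "e", "f"),
    arm = c(0L, 0L, 0L, 1L, 1L, 1L),
    day = c(41, 42, 43, 40, 42, 44),
    area_cm2 = c(3.0, 4.0, 5.0, 2.0, 2.5, 4.5),
    method = "m"
  )
  res <- nonparametric_difference(data, day = 42, window = 3.5)
  x1 <- c(2.0, 2.5, 4.5); x0 <- c(3.0, 4.0, 5.0)
  expect_equal(res$estimate, mean(x1) - mean(x0))
  tt <- t.test(x1, x0)
  expect_equal(c(res$lower, res$upper), tt$conf.int, ignore_attr = TRUE)
  expect_equal(res$n_control, 3L)
})

test_that("relabelled identical arms give a zero nonparametric estimate", {
  base <- tibble::tibble(patient_id = c("a", "b", "c"), arm = 0L,
                         day = 42, area_cm2 = c(3, 4, 5), method = "m")
  mirrored <- dplyr::bind_rows(
    base,
    dplyr::mutate(base, patient_id = paste0(patient_id, "t"), arm = 1L))
  res <- nonparametric_difference(mirrored, day = 42)
  expect_equal(res$estimate, 0)
  expect_equal(res$lower, -res$upper)
})

test_that("nonparametric comparator picks each patient's nearest visit and errors when starved", {
  data <- tibble::tibble(
    patient_id = c("a", "a", "b"), arm = c(0L, 0L, 1L),
    day = c(40, 42, 41), area_cm2 = c(9, 4, 4), method = "m"
  )
  expect_error(nonparametric_difference(data, day = 42),
               "insufficient data")
  # nearest-visit selection: patient a contributes day 42 (area 4), not 40
  wide <- dplyr::bind_rows(data, tibble::tibble(
    patient_id = c("c", "d"), arm = c(0L, 1L), day = 42,
    area_cm2 = c(4.6, 4.6), method = "m"))
  res <- nonparametric_difference(wide, day = 42)
  expect_equal(res$estimate, 0)
})
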