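# WAIC, PSIS-LOO and posterior predictive checks.

test_that("single-draw WAIC has zero penalty and elpd = sum(ll)", {
  ll <- matrix(c(-1.3, -0.7, -2.1), nrow = 1)
  w <- waic(ll)
  expect_equal(woundcurve:::score_value(w, "p_waic"), 0)
  expect_equal(woundcurve:::score_value(w, "elpd_waic"), sum(ll))
})

test_that("two-draw one-observation WAIC matches hand computation", {
  ll <- matrix(log(c(0.5, 0.25)), ncol = 1)
  w <- waic(ll)
  expect_equal(w$pointwise$lppd, log(0.375))
  expect_equal(w$pointwise$p_waic, var(log(c(0.5, 0.25))))
  expect_equal(woundcurve:::score_value(w, "elpd_waic"),
               log(0.375) - var(log(c(0.5, 0.25))))
})

test_that("WAIC is additive over observations", {
  set.seed(1)
  ll <- matrix(rnorm(200, -1, 0.3), 50, 4)
  single <- woundcurve:::score_value(waic(ll), "elpd_waic")
  doubled <- woundcurve:::score_value(waic(cbind(ll, ll)), "elpd_waic")
  expect_equal(doubled, 2 * single)
})

test_that("elpd_waic never exceeds lppd (non-negative penalty)", {
  set.seed(2)
  ll <- matrix(rnorm(1000, -2, 1), 100, 10)
  w <- waic(ll)
  expect_true(all(w$pointwise$elpd_waic <= w$pointwise$lppd + 1e-12))
  expect_true(woundcurve:::score_value(w, "p_waic") >= 0)
})

test_that("zero-variance log-likelihood makes PSIS-LOO equal WAIC exactly", {
  ll <- matrix(rep(c(-1.2, -0.8), each = 150), 150, 2)
  lo <- suppressWarnings(psis_loo(ll))
  wa <- waic(ll)
  expect_equal(woundcurve:::score_value(lo, "elpd_loo"),
               woundcurve:::score_value(wa, "elpd_waic"))
  expect_equal(woundcurve:::score_value(lo, "elpd_loo"), sum(ll[1, ]))
})

test_that("an all-(-Inf) observation column is an error for both criteria", {
  ll <- matrix(rnorm(20), 10, 2)
  ll[, 2] <- -Inf
  expect_error(waic(ll), "-Inf")
  expect_error(suppressWarnings(psis_loo(ll)), "-Inf")
})

test_that("PSIS-LOO matches brute-force exact LOO on a small instance", {
  # tiny instance so each observation can be left out and the model refitted
  trial <- small_trial(n = 8, seed = 17, visits = c(0, 7, 21, 42))
  fit <- quick_fit(trial, "exponential", seed = 17, warmup = 400, iter = 600)
  lo <- suppressWarnings(psis_loo(fit))   # tiny data: high-k flags expected
  held_out <- 1:8
  exact <- vapply(held_out, function(i) {
    refit <- quick_fit(trial[-i, ], "exponential", seed = 17,
                       warmup = 400, iter = 600)
    # elpd_i = log E_post(-i) p(y_i | theta): score obs i against each draw
    d <- refit$draws
    ll_i <- vapply(seq_len(nrow(d)), function(s) {
      spec <- model_spec("exponential", mu = d$mu[s], tau = d$tau[s],
                         omega = d$omega[s], rho0 = d$rho0_1[s],
                         rho1 = d$rho1_1[s])
      # integrate the patient effect via the drawn z for that patient
      pat <- match(trial$patient_id[i], refit$patient_ids)
      alpha <- setNames(d$tau[s] * refit$z[s, pat],
                        as.character(trial$patient_id[i]))
      log_lik_pointwise(spec, alpha, trial[i, ])
    }, numeric(1))
    woundcurve:::logsumexp(ll_i) - log(length(ll_i))
  }, numeric(1))
  psis_i <- lo$pointwise$elpd_loo[held_out]
  # Monte-Carlo standard error of the difference, per observation
  expect_lt(mean(abs(psis_i - exact)), 0.1)
  expect_lt(abs(sum(psis_i) - sum(exact)), 2 * sqrt(sum((psis_i - exact)^2)) + 0.3)
})

test_that("Pareto-k diagnostics are returned and bounded sensibly", {
  trial <- small_trial(n = 12, seed = 23)
  fit <- quick_fit(trial, "square_root", seed = 23, warmup = 200, iter = 200)
  lo <- suppressWarnings(psis_loo(fit))
  expect_equal(nrow(lo$pointwise), nrow(trial))
  expect_true(all(is.na(lo$pointwise$pareto_k) |
                    lo$pointwise$pareto_k < 2))
  expect_equal(lo$n_bad_k,
               sum(lo$pointwise$pareto_k > 0.7, na.rm = TRUE))
})

test_that("the generating family outranks a misspecified one by elpd_loo", {
  truth <- trial_truth("exponential")
  trial <- generate_trial(trial_design(n_patients = 30), truth = truth,
                          seed = 41)
  f_exp <- quick_fit(trial, "exponential", seed = 41)
  f_lin <- quick_fit(trial, "linear", seed = 41)
  cmp <- compare_models(exponential = f_exp, linear = f_lin)
  expect_equal(cmp$model[1], "exponential")
  # LOO and WAIC orderings agree on this well-behaved instance
  expect_equal(order(-cmp$elpd_loo), order(-cmp$elpd_waic))
})

test_that("posterior predictive replicates honour the design-point contract", {
  trial <- small_trial(n = 10, seed = 51)
  fit <- quick_fit(trial, "square_root", seed = 51, warmup = 150, iter = 150)
  ppc <- posterior_predictive_check(fit, ndraws = 30, seed = 1)
  expect_equal(ncol(ppc$y_rep), nrow(trial))
  expect_lte(nrow(ppc$y_rep), 30L)
  expect_true(all(ppc$y_rep > 0))
  p <- autoplot(ppc)
  expect_s3_class(p, "ggplot")
})

test_that("self-generated data lies inside the predictive envelope", {
  trial <- small_trial(n = 24, seed = 61)
  fit <- quick_fit(trial, "square_root", seed = 61)
  ppc <- posterior_predictive_check(fit, ndraws = 50, seed = 2)
  expect_gte(ppc_coverage(ppc), 0.9)
})

test_that("semiparametric fit spreads its replicates at least as widely as the generating family", {
  trial <- small_trial(n = 24, seed = 71)
  fit_gen <- quick_fit(trial, "square_root", seed = 71)
  fit_semi <- quick_fit(trial, "semiparametric", seed = 71)
  sp_gen <- ppc_spread(posterior_predictive_check(fit_gen, seed = 3))
  sp_semi <- ppc_spread(posterior_predictive_check(fit_semi, seed = 3))
  expect_gte(sp_semi, 0.95 * sp_gen)
})
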