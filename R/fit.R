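# Posterior sampling front end: wound_fit() runs the Gibbs/slice sampler over
# multiple chains, assembles a draws tibble, the pointwise log-likelihood
# matrix and convergence diagnostics.

#' Fit the hierarchical wound-area model
#'
#' Samples the posterior of the hierarchical log-linear model
#' `log y_it = beta0 + alpha_i + log f(t; rho_arm) + e_it` for one
#' healing-rate family, using a Metropolis-within-Gibbs sampler (conjugate
#' updates for `mu`, `tau` and the non-centred patient effects; slice
#' sampling for `omega` and each healing-rate parameter). Both arms share
#' `(mu, tau, omega)`; each arm has its own `rho`.
#'
#' @param data A measurement tibble (one measurement method at a time; see
#'   [as_measurement_table()]). A zero-row tibble built with the canonical
#'   columns samples the prior.
#' @param family Healing-rate family name (see [healing_families()]).
#' @param chains Number of chains (>= 2, so split-R-hat is defined).
#' @param warmup,iter Warmup and retained iterations per chain.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`. Identical seed
#'   and configuration give identical draws.
#' @param t_max Wendland rescaling constant (default 100 days).
#' @param basis A [spline_basis()] for the semiparametric family; built
#'   automatically over the observed time range when omitted.
#' @param priors A [prior_spec()].
#' @param loglik If `TRUE` (default) compute the draws-by-observations
#'   pointwise log-likelihood matrix needed by [waic()]/[psis_loo()].
#' @param as_printed Wendland-1 audit form; see [healing_function()].
#' @param slice_w Named numeric slice widths for `omega` and `rho`.
#' @return An object of class `wound_fit`: draws tibble (`.chain`,
#'   `.iteration`, `mu`, `tau`, `omega`, `rho0_*`, `rho1_*`), patient-effect
#'   draws, `loglik` matrix, diagnostics (split-R-hat, effective sample
#'   size) and run metadata.
#' @export
#' @examples
#' \donttest{
#' trial <- generate_trial(trial_design(n_patients = 20), seed = 1)
#' fit <- wound_fit(trial, "square_root", chains = 2, warmup = 200,
#'                  iter = 200, seed = 1)
#' tidy(fit)
#' }
wound_fit <- function(data, family, chains = 4L, warmup = 1000L, iter = 1000L,
                      seed = 1L, t_max = 100, basis = NULL,
                      priors = prior_spec(), loglik = TRUE,
                      as_printed = FALSE,
                      slice_w = c(tau = 0.1, omega = 0.05, rho = 0.01)) {
  family <- match.arg(family, healing_families()$family)
  if (chains < 2L) abort("use at least 2 chains so split-R-hat is defined")
  stopifnot(warmup >= 0L, iter >= 1L)
  if (nrow(data) > 0L) {
    stopifnot(all(mt_required_cols %in% names(data)))
    if (length(unique(data$method)) > 1L) {
      abort("fit one measurement method at a time (filter `method` first)")
    }
  } else {
    inform("zero-row data: sampling the prior")
  }
  if (family == "semiparametric" && is.null(basis)) {
    rng <- if (nrow(data)) range(data$day) else c(0, 70)
    if (diff(rng) <= 0) rng <- c(0, max(rng[2], 1))
    basis <- spline_basis(c(min(0, rng[1]), rng[2]))
  }
  prep <- mcmc_prepare_data(data, family, t_max, basis)
  set.seed(as.integer(seed))
  init <- mcmc_init(prep, family, t_max, priors, basis)

  chain_res <- lapply(seq_len(chains), function(cc) {
    run_chain(prep, family, t_max, priors, n_iter = iter, n_warmup = warmup,
              seed = as.integer(seed) + cc - 1L, init = init,
              as_printed = as_printed, slice_w = slice_w)
  })

  draws_mat <- do.call(rbind, lapply(chain_res, `[[`, "draws"))
  zmat <- do.call(rbind, lapply(chain_res, `[[`, "z"))
  draws <- as_tibble(as.data.frame(draws_mat))
  draws <- dplyr::bind_cols(
    tibble(.chain = rep(seq_len(chains), each = iter),
           .iteration = rep(seq_len(iter), chains)),
    draws
  )

  diag <- fit_diagnostics(draws_mat, chains, iter)
  bad <- diag$parameter[!is.na(diag$rhat) & diag$rhat > 1.01]
  if (length(bad)) {
    warn(paste0("R-hat > 1.01 for: ", paste(bad, collapse = ", "),
                "; consider more iterations"))
  }

  fit <- structure(
    list(draws = draws, z = zmat, patient_ids = prep$ids,
         arm_pat = prep$arm_pat, data = data, family = family,
         t_max = t_max, basis = basis, priors = priors,
         diagnostics = diag,
         meta = list(seed = as.integer(seed), chains = chains,
                     warmup = warmup, iter = iter,
                     n_obs = prep$n_obs, n_patients = prep$n_pat)),
    class = "wound_fit"
  )
  if (loglik && prep$n_obs > 0L) fit$loglik <- loglik_matrix(fit)
  fit
}

# draws x observations pointwise log-likelihood matrix.
loglik_matrix <- function(fit) {
  data <- fit$data
  prep <- mcmc_prepare_data(data, fit$family, fit$t_max, fit$basis)
  d <- fit$draws
  S <- nrow(d)
  k <- (ncol(d) - 5L) / 2L
  rho0 <- as.matrix(d[paste0("rho0_", seq_len(k))])
  rho1 <- as.matrix(d[paste0("rho1_", seq_len(k))])
  ll <- matrix(-Inf, S, prep$n_obs)
  for (s in seq_len(S)) {
    lf0 <- mcmc_logf_ut(fit$family, rho0[s, ], prep$ut, fit$t_max, prep$B_ut)
    lf1 <- mcmc_logf_ut(fit$family, rho1[s, ], prep$ut, fit$t_max, prep$B_ut)
    if (is.null(lf0) || is.null(lf1)) next
    lf_obs <- numeric(prep$n_obs)
    i0 <- prep$idx_arm[[1L]]; i1 <- prep$idx_arm[[2L]]
    lf_obs[i0] <- lf0[prep$t_idx[i0]]
    lf_obs[i1] <- lf1[prep$t_idx[i1]]
    m <- d$mu[s] - d$omega[s]^2 / 2 + d$tau[s] * fit$z[s, prep$pid] + lf_obs
    ll[s, ] <- dnorm(prep$L, m, d$omega[s], log = TRUE)
  }
  ll
}

# Split-R-hat (each chain halved) and effective sample size via coda.
fit_diagnostics <- function(draws_mat, chains, iter) {
  params <- colnames(draws_mat)
  half <- iter %/% 2L
  rhat <- vapply(params, function(p) {
    x <- matrix(draws_mat[, p], nrow = iter, ncol = chains)
    if (half < 2L) return(NA_real_)
    splits <- cbind(x[seq_len(half), , drop = FALSE],
                    x[seq_len(half) + (iter - half), , drop = FALSE])
    m <- ncol(splits); n <- nrow(splits)
    means <- colMeans(splits)
    vars <- apply(splits, 2L, var)
    B <- n * var(means)
    W <- mean(vars)
    if (W == 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  ess <- vapply(params, function(p) {
    x <- draws_mat[, p]
    if (sd(x) == 0) return(NA_real_)
    as.numeric(coda::effectiveSize(x))
  }, numeric(1))
  tibble(parameter = params, rhat = unname(rhat), ess = unname(ess))
}

#' @export
print.wound_fit <- function(x, ...) {
  cat("<wound_fit>", x$family, "model |", x$meta$n_obs, "observations,",
      x$meta$n_patients, "patients\n")
  cat("  ", x$meta$chains, "chains x", x$meta$iter, "draws (",
      x$meta$warmup, "warmup ), seed", x$meta$seed, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy posterior summaries of a fitted wound model
#'
#' @param x A `wound_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: posterior mean, sd,
#'   2.5/97.5% quantiles, split-R-hat and effective sample size.
#' @method tidy wound_fit
#' @export
tidy.wound_fit <- function(x, ...) {
  params <- setdiff(names(x$draws), c(".chain", ".iteration"))
  out <- purrr::map_dfr(params, function(p) {
    v <- x$draws[[p]]
    tibble(term = p, estimate = mean(v), std.error = sd(v),
           conf.low = unname(quantile(v, 0.025)),
           conf.high = unname(quantile(v, 0.975)))
  })
  left_join(out, x$diagnostics, by = c(term = "parameter"))
}

#' One-row summary of a fitted wound model
#'
#' @param x A `wound_fit`.
#' @param ... Unused.
#' @return A tibble with the family, data size, sampler settings and
#'   worst-case convergence diagnostics.
#' @method glance wound_fit
#' @export
glance.wound_fit <- function(x, ...) {
  tibble(family = x$family, nobs = x$meta$n_obs,
         n_patients = x$meta$n_patients, chains = x$meta$chains,
         draws = nrow(x$draws),
         max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
         min_ess = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)))
}

# Arm-specific rho draws as an S x k matrix.
fit_rho_draws <- function(fit, arm) {
  k <- (ncol(fit$draws) - 5L) / 2L
  pref <- if (arm == 1) "rho1_" else "rho0_"
  as.matrix(fit$draws[paste0(pref, seq_len(k))])
}

# f evaluated on a time grid for every draw: S x length(t) matrix.
fit_f_draws <- function(fit, t, arm, deriv = FALSE) {
  rho <- fit_rho_draws(fit, arm)
  B <- if (fit$family == "semiparametric") {
    sb_matrix(fit$basis, t, deriv = as.integer(deriv))
  } else NULL
  raw <- if (deriv) hf_deriv_raw else hf_value_raw
  res <- apply(rho, 1L, function(r) raw(fit$family, r, t, fit$t_max, B))
  if (length(t) == 1L) matrix(res, ncol = 1L) else t(res)
}
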