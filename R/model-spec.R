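# The hierarchical log-linear model of wound area:
#
#   log y_i(t) = beta0 + alpha_i + log f(t; rho_arm) + e_it
#
# with alpha_i ~ N(0, tau^2) a patient random effect and e_it ~ N(0, omega^2)
# the multiplicative (lognormal) measurement error on the log scale. The
# model is parameterised in (mu, tau, omega) with beta0 = mu - omega^2/2:
# this makes the measurement-error factor mean-one, E[exp(e - omega^2/2)]
# exp(omega^2/2) = 1, so measurements are correct on average, and the
# marginal mean area is exp(mu + tau^2/2) f(t).

#' Prior specification for the hierarchical wound model
#'
#' Weakly informative defaults: `mu ~ N(1, 2^2)` (baseline mean log-area,
#' spanning roughly 0-20 cm² on the natural scale), `tau ~ N(0, 2^2)`
#' truncated to `[0, Inf)` and `omega ~ N(0, 0.5^2)` truncated to `[0, Inf)`
#' (allowing measurement noise up to around +/-100%). The healing-rate
#' parameters get independent `N(0, rho_sd^2)` priors; the default
#' `rho_sd = 1` is wide relative to per-day rates of realistic magnitude.
#'
#' @param mu_mean,mu_sd Normal prior for `mu`.
#' @param tau_sd Half-normal prior scale for `tau`.
#' @param omega_sd Half-normal prior scale for `omega`.
#' @param rho_sd Normal prior scale for each healing-rate parameter.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu_mean = 1, mu_sd = 2, tau_sd = 2, omega_sd = 0.5,
                       rho_sd = 1) {
  stopifnot(mu_sd > 0, tau_sd > 0, omega_sd > 0, rho_sd > 0)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd, tau_sd = tau_sd,
                 omega_sd = omega_sd, rho_sd = rho_sd),
            class = "prior_spec")
}

#' Full model specification
#'
#' A parameterised instance of the hierarchical model: a healing-rate family
#' shared by both arms, shared nuisance parameters `(mu, tau, omega)` and
#' arm-specific healing-rate parameter vectors `rho0` (control) and `rho1`
#' (treatment). Randomisation justifies the common baseline distribution.
#'
#' @param family Healing-rate family name (see [healing_families()]).
#' @param mu Mean of the true baseline log-area distribution.
#' @param tau SD of the true baseline log-area across patients (`>= 0`).
#' @param omega SD of the multiplicative measurement error on the log scale
#'   (`>= 0`).
#' @param rho0,rho1 Healing-rate parameters for the control and treatment
#'   arms.
#' @param t_max Rescaling constant for the Wendland families (default 100).
#' @param basis [spline_basis()] for the semiparametric family.
#' @param priors A [prior_spec()].
#' @param as_printed Passed to [healing_function()] (Wendland-1 audit form).
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' spec <- model_spec("square_root", mu = 1.5, tau = 0.5, omega = 0.3,
#'                    rho0 = c(-0.004, -0.07), rho1 = c(-0.004, -0.07))
#' beta0(spec)
model_spec <- function(family, mu, tau, omega, rho0, rho1 = rho0,
                       t_max = 100, basis = NULL, priors = prior_spec(),
                       as_printed = FALSE) {
  stopifnot(tau >= 0, omega >= 0)
  f0 <- healing_function(family, rho0, t_max = t_max, basis = basis,
                         as_printed = as_printed)
  f1 <- healing_function(family, rho1, t_max = t_max, basis = basis,
                         as_printed = as_printed)
  structure(
    list(family = f0$family, mu = mu, tau = tau, omega = omega,
         rho = list(`0` = as.numeric(rho0), `1` = as.numeric(rho1)),
         t_max = t_max, basis = basis, priors = priors,
         as_printed = isTRUE(as_printed), f0 = f0, f1 = f1),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$family, "| mu =", signif(x$mu, 4),
      "tau =", signif(x$tau, 4), "omega =", signif(x$omega, 4), "\n")
  cat("  rho0: [", paste(signif(x$rho$`0`, 4), collapse = ", "), "]\n")
  cat("  rho1: [", paste(signif(x$rho$`1`, 4), collapse = ", "), "]\n")
  invisible(x)
}

#' Model intercept implied by the mean-one error convention
#'
#' `beta0 = mu - omega^2 / 2`: the intercept of the log-linear model once the
#' lognormal measurement error is centred to have mean one on the natural
#' scale.
#'
#' @param spec A [model_spec()].
#' @return A scalar.
#' @export
beta0 <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  spec$mu - spec$omega^2 / 2
}

hf_for_arm <- function(spec, arm) if (arm == 1) spec$f1 else spec$f0

#' Pointwise log-likelihood of a measurement table
#'
#' Evaluates the log-density of each observed log-area under
#' `Normal(beta0 + alpha_i + log f(t; rho_arm), omega^2)`. The density is on
#' the log-area scale: the lognormal Jacobian term `-log(y)` is parameter-free
#' and identical across all healing-rate families, so it cancels from every
#' LOO/WAIC *difference*; absolute elpd values carry this convention.
#'
#' Observations at times where `f(t; rho) <= 0` get a `-Inf` entry (soft
#' rejection) rather than raising an error, because the admissible parameter
#' region of the linear-scale families depends on the observed time range.
#' Rows flagged `censored` contribute the left-tail probability
#' `Phi((log(area) - mean)/omega)` instead of a density.
#'
#' @param spec A [model_spec()].
#' @param alpha Named numeric vector of patient random effects; names must
#'   cover every `patient_id` in `data`.
#' @param data A measurement tibble (see [as_measurement_table()]).
#' @return Numeric vector, one log-likelihood value per row of `data`.
#' @export
log_lik_pointwise <- function(spec, alpha, data) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$omega <= 0) abort("`omega` must be > 0 to evaluate the likelihood")
  ids <- as.character(data$patient_id)
  if (!all(unique(ids) %in% names(alpha))) {
    abort("`alpha` must be named and cover every patient_id in `data`")
  }
  a <- alpha[ids]
  f <- numeric(nrow(data))
  for (arm in c(0L, 1L)) {
    idx <- which(data$arm == arm)
    if (length(idx)) f[idx] <- hf_eval(hf_for_arm(spec, arm), data$day[idx])
  }
  ll <- rep(-Inf, nrow(data))
  ok <- f > 0
  m <- beta0(spec) + a[ok] + log(f[ok])
  cens <- if ("censored" %in% names(data)) data$censored else rep(FALSE, nrow(data))
  dens <- ok & !cens
  ll[dens] <- dnorm(log(data$area_cm2[dens]),
                    mean = (beta0(spec) + a + log(pmax(f, .Machine$double.xmin)))[dens],
                    sd = spec$omega, log = TRUE)
  lc <- ok & cens
  if (any(lc)) {
    ll[lc] <- pnorm(log(data$area_cm2[lc]),
                    mean = (beta0(spec) + a + log(f))[lc],
                    sd = spec$omega, log.p = TRUE)
  }
  unname(ll)
}

#' Simulate measurements from a fully specified model
#'
#' Draws from the data-generating process `y_i(t) = y*_i(0) f(t; rho) u_i(t)`
#' at the design points supplied: true baseline log-areas
#' `w_i(0) ~ N(mu, tau^2)`, lognormal errors `u = exp(eps)` with
#' `eps ~ N(-omega^2/2, omega^2)` so `E[u] = 1`.
#'
#' @param spec A [model_spec()].
#' @param design A data frame with columns `patient_id`, `arm`, `day` (and
#'   optionally `method`): one row per planned measurement.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A measurement tibble with an added hidden attribute `"w0"` (the
#'   true baseline log-areas, for recovery tests).
#' @export
simulate_wounds <- function(spec, design, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.data.frame(design) || nrow(design) == 0L) {
    abort("`design` must be a nonempty data frame (patient_id, arm, day)")
  }
  stopifnot(all(c("patient_id", "arm", "day") %in% names(design)))
  set.seed(as.integer(seed))
  ids <- unique(as.character(design$patient_id))
  w0 <- rnorm(length(ids), spec$mu, spec$tau)
  names(w0) <- ids
  f <- numeric(nrow(design))
  for (arm in c(0L, 1L)) {
    idx <- which(design$arm == arm)
    if (length(idx)) f[idx] <- hf_eval(hf_for_arm(spec, arm), design$day[idx])
  }
  if (any(f <= 0)) {
    abort("f(t; rho) <= 0 at some design point; choose parameters with f > 0 over the schedule")
  }
  eps <- rnorm(nrow(design), -spec$omega^2 / 2, spec$omega)
  out <- as_tibble(design)
  out$area_cm2 <- unname(exp(w0[as.character(design$patient_id)]) * f * exp(eps))
  if (!"method" %in% names(out)) out$method <- "simulated"
  out <- out[, unique(c(mt_required_cols, names(out)))]
  attr(out, "w0") <- w0
  out
}
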