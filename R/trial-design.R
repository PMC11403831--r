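# Synthetic two-arm ulcer-healing trials. The default design mirrors a
# 130-patient, 1:1 randomised trial with dressing changes (and area
# measurements) every three or four days up to day 70, baseline areas
# restricted to 2-20 cm2 by the inclusion criteria, and up to three
# measurement methods per image.

#' Visit schedule with alternating 3/4-day gaps
#'
#' Days 0, 3, 7, 10, 14, ... ("twice weekly") up to `horizon`.
#'
#' @param horizon Last day of follow-up (default 70).
#' @return Numeric vector of visit days.
#' @export
twice_weekly_schedule <- function(horizon = 70) {
  days <- cumsum(c(0, rep(c(3, 4), length.out = ceiling(2 * horizon / 7) + 2)))
  days[days <= horizon]
}

#' Trial design for the synthetic-data generator
#'
#' @param n_patients Number of patients, randomised 1:1 (default 130).
#' @param visit_schedule Measurement days (default [twice_weekly_schedule()]).
#' @param baseline_range Inclusion criterion on true baseline area in cm²
#'   (default `c(2, 20)`); the generator truncates the baseline lognormal to
#'   this interval. Set `truncate_baseline = FALSE` for exact-model recovery
#'   experiments (truncation is realistic misspecification).
#' @param methods A data frame with columns `method` and `omega` giving the
#'   per-method lognormal measurement-error SD, or `NULL` to use a single
#'   method with the generating model's `omega`.
#' @param dropout_rate Per-visit probability that a patient drops out from
#'   that visit onward (default 0).
#' @param healing_stop If `TRUE`, a patient's visits stop once their *true*
#'   area first falls below `healing_threshold`.
#' @param healing_threshold Healed-area threshold in cm² (default 0.25).
#' @param truncate_baseline Apply the `baseline_range` truncation (default
#'   `TRUE`).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_patients = 130L,
                         visit_schedule = twice_weekly_schedule(70),
                         baseline_range = c(2, 20),
                         methods = NULL,
                         dropout_rate = 0,
                         healing_stop = FALSE,
                         healing_threshold = 0.25,
                         truncate_baseline = TRUE) {
  stopifnot(n_patients >= 2L, length(visit_schedule) >= 1L,
            !is.unsorted(visit_schedule), visit_schedule[1] >= 0,
            dropout_rate >= 0, dropout_rate < 1, healing_threshold > 0)
  if (length(baseline_range) != 2L || diff(baseline_range) <= 0 ||
      baseline_range[1] <= 0) {
    abort("`baseline_range` must be an increasing positive interval")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         visit_schedule = as.numeric(visit_schedule),
         baseline_range = as.numeric(baseline_range),
         methods = methods, dropout_rate = dropout_rate,
         healing_stop = isTRUE(healing_stop),
         healing_threshold = healing_threshold,
         truncate_baseline = isTRUE(truncate_baseline)),
    class = "trial_design"
  )
}

#' Default generating truth for synthetic trials
#'
#' Study-condition defaults: `mu = 1.5` (mean baseline area
#' `exp(1.5) = 4.48` cm², in line with baseline means of 4-5 cm² in
#' ulcer-healing trials of this kind), `tau = 0.5`, `omega = 0.3`, and a
#' square-root healing function with `rho = (-0.004, -0.07)` in both arms
#' (monotone healing, area positive over the 70-day schedule). Override any
#' field to generate an effect.
#'
#' @inheritParams model_spec
#' @return A [model_spec()].
#' @export
trial_truth <- function(family = "square_root", mu = 1.5, tau = 0.5,
                        omega = 0.3, rho0 = NULL, rho1 = NULL,
                        t_max = 100, basis = NULL) {
  default_rho <- switch(family,
    exponential = -log(0.15) / 70,     # ~85% area reduction by day 70
    gompertz = 0.02,
    linear = -0.012,
    quadratic = c(-0.016, 0.0001),
    square_root = c(-0.004, -0.07),
    wendland0 = 2,
    wendland1 = 2,
    semiparametric = NULL,
    log_linear = -0.012,
    log_quadratic = c(-0.016, 0.0001),
    log_square_root = c(-0.004, -0.07)
  )
  if (is.null(rho0)) rho0 <- default_rho
  if (is.null(rho1)) rho1 <- rho0
  if (is.null(rho0)) abort("supply `rho0` for the semiparametric family")
  model_spec(family, mu = mu, tau = tau, omega = omega,
             rho0 = rho0, rho1 = rho1, t_max = t_max, basis = basis)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (any(mean < lower | mean > upper)) {
      abort("degenerate baseline distribution falls outside the inclusion range")
    }
    return(rep(mean, n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) {
    abort("baseline truncation interval has negligible probability under (mu, tau)")
  }
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a full synthetic trial
#'
#' Applies the model's data-generating process to a [trial_design()]:
#' baseline log-areas `w_i(0) ~ N(mu, tau^2)` (truncated so areas respect the
#' inclusion range when `truncate_baseline` is on), arm assignment 1:1,
#' per-visit per-method areas with independent lognormal measurement error,
#' optional dropout, and optional stopping of visits once the true area
#' crosses the healed threshold.
#'
#' @param design A [trial_design()].
#' @param truth A [model_spec()] giving the generating parameters (default
#'   [trial_truth()]).
#' @param seed Integer seed.
#' @return A measurement tibble with attribute `"truth"` (the generating
#'   [model_spec()]) and `"w0"` (true baseline log-areas).
#' @export
#' @examples
#' trial <- generate_trial(trial_design(n_patients = 10), seed = 1)
#' dplyr::count(trial, arm)
generate_trial <- function(design = trial_design(), truth = trial_truth(),
                           seed = 1L) {
  stopifnot(inherits(design, "trial_design"), inherits(truth, "model_spec"))
  set.seed(as.integer(seed))
  n <- design$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  arm <- rep(c(0L, 1L), length.out = n)[sample.int(n)]
  lo <- log(design$baseline_range[1]); hi <- log(design$baseline_range[2])
  w0 <- if (design$truncate_baseline) {
    rnorm_trunc(n, truth$mu, truth$tau, lo, hi)
  } else {
    rnorm(n, truth$mu, truth$tau)
  }
  names(w0) <- ids

  methods <- design$methods %||%
    data.frame(method = "simulated", omega = truth$omega)
  stopifnot(all(c("method", "omega") %in% names(methods)))

  sched <- design$visit_schedule
  f_by_arm <- lapply(c(0L, 1L), function(a) hf_eval(hf_for_arm(truth, a), sched))
  if (any(unlist(f_by_arm) <= 0)) {
    abort("truth has f(t) <= 0 within the visit schedule")
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- f_by_arm[[arm[i] + 1L]]
    keep <- rep(TRUE, length(sched))
    if (design$healing_stop) {
      true_area <- exp(w0[i]) * f
      healed_at <- which(true_area < design$healing_threshold)
      if (length(healed_at)) keep[seq_along(sched) > healed_at[1]] <- FALSE
    }
    if (design$dropout_rate > 0) {
      drops <- rbinom(length(sched) - 1L, 1L, design$dropout_rate)
      if (any(drops == 1L)) keep[seq_along(sched) > which(drops == 1L)[1]] <- FALSE
    }
    vis <- which(keep)
    per_method <- lapply(seq_len(nrow(methods)), function(m) {
      eps <- rnorm(length(vis), -methods$omega[m]^2 / 2, methods$omega[m])
      tibble(patient_id = ids[i], arm = arm[i], day = sched[vis],
             area_cm2 = exp(w0[i]) * f[vis] * exp(eps),
             method = methods$method[m])
    })
    rows[[i]] <- bind_rows(per_method)
  }
  out <- bind_rows(rows)
  attr(out, "truth") <- truth
  attr(out, "w0") <- w0
  out
}
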