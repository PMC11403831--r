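# Treatment-effect estimands derived from posterior draws. All return an
# `effect_curve` tibble: time grid, posterior mean and 2.5/97.5% quantiles.
#
# Closed forms (beta0 = mu - omega^2/2):
#   delta1(t) = exp(beta0 + (tau^2 + omega^2)/2) (f1(t) - f0(t))
#             = exp(mu + tau^2/2) (f1(t) - f0(t))    [cm^2]
#   delta2(t) = f1(t) - f0(t)                         [dimensionless]

new_effect_curve <- function(df, estimand, units) {
  structure(as_tibble(df), estimand = estimand, units = units,
            class = c("effect_curve", class(as_tibble(df))))
}

summarise_draw_matrix <- function(M, t, estimand, units, extra = NULL) {
  bad <- !stats::complete.cases(M) | apply(M, 1L, function(r) any(!is.finite(r)))
  if (any(bad)) {
    inform(sprintf("dropping %d draw(s) with invalid healing-function values", sum(bad)))
    M <- M[!bad, , drop = FALSE]
  }
  if (nrow(M) == 0L) abort("no valid draws left for this estimand")
  df <- tibble(
    time = t,
    mean = colMeans(M),
    lower = apply(M, 2L, quantile, 0.025),
    upper = apply(M, 2L, quantile, 0.975)
  )
  if (!is.null(extra)) df <- dplyr::bind_cols(extra, df)
  new_effect_curve(df, estimand, units)
}

#' Mean difference in wound area over time (cm²)
#'
#' Per posterior draw and time point computes
#' `exp(beta0 + (tau^2 + omega^2)/2) * (f1(t; rho1) - f0(t; rho0))` with
#' `beta0 = mu - omega^2/2` — i.e. the marginal mean baseline area times the
#' difference in proportionate area — then summarises across draws.
#'
#' @param fit A `wound_fit`.
#' @param t_grid Time grid in days (default 0-70 by 1).
#' @return An `effect_curve` tibble (time, mean, lower, upper), units cm².
#' @export
delta1 <- function(fit, t_grid = seq(0, 70, by = 1)) {
  stopifnot(inherits(fit, "wound_fit"))
  d <- fit$draws
  scale <- exp((d$mu - d$omega^2 / 2) + (d$tau^2 + d$omega^2) / 2)
  M <- scale * (fit_f_draws(fit, t_grid, 1) - fit_f_draws(fit, t_grid, 0))
  summarise_draw_matrix(M, t_grid, "delta1", "cm2")
}

#' Mean difference in proportionate wound area over time
#'
#' `delta2(t) = f1(t; rho1) - f0(t; rho0)` per draw. With `normalize = TRUE`
#' each arm's function is divided by its own value at `t = 0`
#' (`f1(t)/f1(0) - f0(t)/f0(0)`), giving a genuinely proportionate contrast
#' even for families whose fitted `f(0)` differs from one (the log-scale
#' families start at `e`).
#'
#' @inheritParams delta1
#' @param normalize Divide each arm by its `f(0)` (default `FALSE`, the
#'   plain difference).
#' @return An `effect_curve` tibble, dimensionless.
#' @export
delta2 <- function(fit, t_grid = seq(0, 70, by = 1), normalize = FALSE) {
  stopifnot(inherits(fit, "wound_fit"))
  F1 <- fit_f_draws(fit, t_grid, 1)
  F0 <- fit_f_draws(fit, t_grid, 0)
  if (normalize) {
    F1 <- F1 / as.numeric(fit_f_draws(fit, 0, 1))
    F0 <- F0 / as.numeric(fit_f_draws(fit, 0, 0))
  }
  summarise_draw_matrix(F1 - F0, t_grid, "delta2", "proportion")
}

#' Difference in healing rates over time (cm²/day)
#'
#' Reconstructed from the model's first principles (closed forms for these
#' rate contrasts are not part of the published model statement):
#' instantaneous mode is `exp(mu + tau^2/2) (f1'(t) - f0'(t))`; average mode
#' up to time `T` is `exp(mu + tau^2/2) ((f1(T) - f1(0)) - (f0(T) - f0(0)))/T`.
#' As `T -> 0` the average mode converges to the instantaneous one for
#' smooth families.
#'
#' @inheritParams delta1
#' @param mode `"instantaneous"` or `"average"`.
#' @return An `effect_curve` tibble, units cm²/day.
#' @export
rate_difference <- function(fit, t_grid = seq(1, 70, by = 1),
                            mode = c("instantaneous", "average")) {
  stopifnot(inherits(fit, "wound_fit"))
  mode <- match.arg(mode)
  if (any(t_grid <= 0)) {
    abort("rate estimands need t > 0 (square-root derivatives are singular at 0)")
  }
  d <- fit$draws
  scale <- exp(d$mu + d$tau^2 / 2)
  if (mode == "instantaneous") {
    M <- scale * (fit_f_draws(fit, t_grid, 1, deriv = TRUE) -
                  fit_f_draws(fit, t_grid, 0, deriv = TRUE))
  } else {
    F1 <- fit_f_draws(fit, t_grid, 1); F0 <- fit_f_draws(fit, t_grid, 0)
    f1_0 <- as.numeric(fit_f_draws(fit, 0, 1))
    f0_0 <- as.numeric(fit_f_draws(fit, 0, 0))
    M <- scale * sweep(sweep(F1, 1L, f1_0) - sweep(F0, 1L, f0_0), 2L,
                       t_grid, "/")
  }
  summarise_draw_matrix(M, t_grid, paste0("rate_", mode), "cm2/day")
}

#' Proportion of wounds healed over time, by arm
#'
#' Reconstructed survival-type estimand: under the model the *true*
#' (measurement-error-free) area at time t is `exp(w_i(0)) f(t)` with
#' `w_i(0) ~ N(mu, tau^2)`, so the proportion healed (true area at or below
#' threshold `c`) is `Phi((log c - mu - log f(t)) / tau)`. Draws with
#' `tau = 0` degenerate to a step function (value 0.5 exactly at the
#' boundary). Compactly supported families reach proportion 1 at `t_max`.
#'
#' @inheritParams delta1
#' @param threshold Healed-area threshold `c` in cm² (default 0.25, a
#'   near-complete re-epithelialisation proxy; user-set, not a published
#'   value).
#' @return An `effect_curve` tibble with an `arm` column covering `"0"`,
#'   `"1"` and `"difference"` (treatment minus control).
#' @export
proportion_healed <- function(fit, t_grid = seq(0, 70, by = 1),
                              threshold = 0.25) {
  stopifnot(inherits(fit, "wound_fit"), threshold > 0)
  d <- fit$draws
  arm_curve <- function(arm) {
    f <- fit_f_draws(fit, t_grid, arm)
    bad <- apply(f, 1L, function(r) any(!is.finite(r) | r < 0))
    lf <- log(pmax(f, 0))                       # f = 0 -> -Inf -> healed
    z <- (log(threshold) - d$mu - lf) / d$tau
    P <- pnorm(z)
    degenerate <- d$tau == 0
    if (any(degenerate)) {
      arg <- (log(threshold) - d$mu - lf)[degenerate, , drop = FALSE]
      P[degenerate, ] <- ifelse(arg > 1e-12, 1, ifelse(arg < -1e-12, 0, 0.5))
    }
    P[bad, ] <- NA_real_
    P
  }
  P0 <- arm_curve(0); P1 <- arm_curve(1)
  out <- bind_rows(
    summarise_draw_matrix(P0, t_grid, "proportion_healed", "proportion",
                          extra = tibble(arm = rep("0", length(t_grid)))),
    summarise_draw_matrix(P1, t_grid, "proportion_healed", "proportion",
                          extra = tibble(arm = rep("1", length(t_grid)))),
    summarise_draw_matrix(P1 - P0, t_grid, "proportion_healed", "proportion",
                          extra = tibble(arm = rep("difference", length(t_grid))))
  )
  new_effect_curve(out, "proportion_healed", "proportion")
}

#' Non-parametric difference in mean area at a landmark day
#'
#' The comparator estimator: each patient contributes their single
#' measurement nearest to `day` within `day ± window`; the arms are compared
#' by a Welch difference in means with a t-interval. Used to study how much
#' precision the model-based `delta1` gains over a fixed-time comparison.
#'
#' @param data A measurement tibble (one method).
#' @param day Landmark day (default 42).
#' @param window Half-width of the selection window in days (default 3.5,
#'   one visit gap).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: estimate (treatment minus control, cm²), lower,
#'   upper, and per-arm patient counts.
#' @export
nonparametric_difference <- function(data, day = 42, window = 3.5,
                                     conf_level = 0.95) {
  stopifnot(all(mt_required_cols %in% names(data)))
  sel <- data %>%
    mutate(dist = abs(.data$day - !!day)) %>%
    filter(.data$dist <= !!window) %>%
    group_by(.data$patient_id) %>%
    slice_min(.data$dist, n = 1L, with_ties = FALSE) %>%
    ungroup()
  n0 <- sum(sel$arm == 0L); n1 <- sum(sel$arm == 1L)
  if (n0 < 2L || n1 < 2L) {
    abort(sprintf(
      "insufficient data near day %g: %d control, %d treatment patient(s)",
      day, n0, n1))
  }
  tt <- t.test(sel$area_cm2[sel$arm == 1L], sel$area_cm2[sel$arm == 0L],
               conf.level = conf_level)
  tibble(estimate = unname(tt$estimate[1] - tt$estimate[2]),
         lower = tt$conf.int[1], upper = tt$conf.int[2],
         n_control = n0, n_treatment = n1, df = unname(tt$parameter))
}

#' Posterior healing-rate functions by arm
#'
#' Summarises `f(t; rho)` for each arm across draws; handy for Fig.-2-style
#' plots of fitted curves with credible bands over the raw data.
#'
#' @inheritParams delta1
#' @return An `effect_curve` tibble with an `arm` column.
#' @export
fitted_curves <- function(fit, t_grid = seq(0, 70, by = 1)) {
  stopifnot(inherits(fit, "wound_fit"))
  out <- bind_rows(
    summarise_draw_matrix(fit_f_draws(fit, t_grid, 0), t_grid, "f", "proportion",
                          extra = tibble(arm = rep("0", length(t_grid)))),
    summarise_draw_matrix(fit_f_draws(fit, t_grid, 1), t_grid, "f", "proportion",
                          extra = tibble(arm = rep("1", length(t_grid))))
  )
  new_effect_curve(out, "healing_function", "proportion")
}
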