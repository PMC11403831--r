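# ggplot2 displays for the package's result types.

#' Plot an effect curve with its credible band
#'
#' @param object An `effect_curve` (from [delta1()], [delta2()],
#'   [rate_difference()], [proportion_healed()] or [fitted_curves()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot effect_curve
#' @export
autoplot.effect_curve <- function(object, ...) {
  estimand <- attr(object, "estimand")
  units <- attr(object, "units")
  ylab <- switch(estimand,
    delta1 = expression(delta[1] ~ (cm^2)),
    delta2 = expression(delta[2]),
    proportion_healed = "proportion healed",
    healing_function = "proportionate area f(t)",
    paste0(estimand, " (", units, ")"))
  p <- ggplot(object, aes(x = .data$time, y = .data$mean))
  if ("arm" %in% names(object)) {
    p <- p +
      geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper,
                      fill = .data$arm), alpha = 0.2) +
      geom_line(aes(colour = .data$arm))
  } else {
    p <- p +
      geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                  fill = "steelblue", alpha = 0.25) +
      geom_line(colour = "steelblue") +
      geom_hline(yintercept = 0, linetype = 2, colour = "grey40")
  }
  p + labs(x = "days post-randomisation", y = ylab) + theme_minimal()
}

#' Density-overlay posterior predictive check plot
#'
#' Replicated-dataset log-area densities in blue over the observed density
#' in red, the same display used for graphical model checking.
#'
#' @param object A `wound_ppc` from [posterior_predictive_check()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wound_ppc
#' @export
autoplot.wound_ppc <- function(object, ...) {
  reps <- purrr::map_dfr(seq_len(nrow(object$y_rep)), function(r) {
    tibble(rep = r, log_area = log(object$y_rep[r, ]))
  })
  obs <- tibble(log_area = log(object$data$area_cm2))
  ggplot() +
    geom_density(data = reps,
                 aes(x = .data$log_area, group = .data$rep),
                 colour = "steelblue", alpha = 0.3, linewidth = 0.3) +
    geom_density(data = obs, aes(x = .data$log_area),
                 colour = "red", linewidth = 0.9) +
    labs(x = expression(log ~ area ~ (cm^2)), y = "density",
         title = paste("posterior predictive check:", object$family)) +
    theme_minimal()
}

#' Fitted healing curves over the raw data
#'
#' Fig.-2-style display: per-arm posterior mean of `f(t)` with 95% credible
#' bands, overlaid on the observed proportionate areas (each measurement
#' divided by the patient's earliest measurement).
#'
#' @param object A `wound_fit`.
#' @param t_grid Time grid in days.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wound_fit
#' @export
autoplot.wound_fit <- function(object, t_grid = seq(0, 70, by = 1), ...) {
  curves <- fitted_curves(object, t_grid)
  pts <- object$data %>%
    group_by(.data$patient_id) %>%
    mutate(prop_area = .data$area_cm2 /
             .data$area_cm2[which.min(.data$day)]) %>%
    ungroup() %>%
    mutate(arm = as.character(.data$arm))
  autoplot(curves) +
    geom_point(data = pts, aes(x = .data$day, y = .data$prop_area,
                               colour = .data$arm),
               alpha = 0.25, size = 0.7) +
    labs(title = paste("fitted", object$family, "healing functions"))
}
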