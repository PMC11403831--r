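# Healing-rate functions f(t; rho): the mean proportionate wound area at time
# t relative to baseline. Eleven parametric families are supported; the two
# Wendland families are compactly supported on [0, t_max] and reach exactly
# zero there, the three log-scale families start at f(0) = e.

#' Registry of healing-rate function families
#'
#' Lists the canonical family names together with the number of parameters
#' each takes (`NA` for the semiparametric family, whose arity is the number
#' of spline basis columns).
#'
#' @return A tibble with columns `family`, `n_params`, `log_scale` and
#'   `compact_support`.
#' @export
#' @examples
#' healing_families()
healing_families <- function() {
  tibble::tibble(
    family = c(
      "exponential", "gompertz", "linear", "quadratic", "square_root",
      "wendland0", "wendland1", "semiparametric",
      "log_linear", "log_quadratic", "log_square_root"
    ),
    n_params = c(1L, 1L, 1L, 2L, 2L, 1L, 1L, NA_integer_, 1L, 2L, 2L),
    log_scale = c(rep(FALSE, 8L), rep(TRUE, 3L)),
    compact_support = c(rep(FALSE, 5L), TRUE, TRUE, rep(FALSE, 4L))
  )
}

hf_arity <- function(family, basis = NULL) {
  fam <- healing_families()
  k <- fam$n_params[match(family, fam$family)]
  if (is.na(k)) {
    if (is.null(basis)) {
      abort("the semiparametric family needs an attached spline basis")
    }
    k <- basis$basis_count
  }
  as.integer(k)
}

#' Construct a healing-rate function specification
#'
#' Bundles a family name, its parameter vector `rho` and the conventions
#' needed to evaluate it: the time-rescaling constant `t_max` for the
#' compactly supported Wendland families and a [spline_basis()] for the
#' semiparametric family.
#'
#' @param family One of the names in [healing_families()].
#' @param rho Numeric parameter vector; its length must match the family
#'   arity (the basis size for `"semiparametric"`).
#' @param t_max Positive rescaling constant: Wendland families are evaluated
#'   at `t / t_max` so that the mean trajectory reaches exactly zero at
#'   `t = t_max`. Default 100 days. Ignored by the other families.
#' @param basis A [spline_basis()]; required for `"semiparametric"`.
#' @param as_printed Logical; the Wendland-1 family defaults to the compactly
#'   supported form `(1 + (p+1)s) (1 - s)_+^(p+1)`. Setting `as_printed =
#'   TRUE` switches to the variant `(1 + (p+1)s) (1 + s)^(p+1)`, which does
#'   not vanish at the support boundary; it is provided for auditing only.
#' @return An object of class `healing_function`.
#' @export
#' @examples
#' hf <- healing_function("square_root", rho = c(-0.01, -0.05))
#' hf_eval(hf, c(0, 4, 25))
healing_function <- function(family, rho, t_max = 100, basis = NULL,
                             as_printed = FALSE) {
  family <- match.arg(family, healing_families()$family)
  if (!is.numeric(rho) || anyNA(rho)) abort("`rho` must be numeric without NA")
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max <= 0) {
    abort("`t_max` must be a positive scalar")
  }
  if (family == "semiparametric") {
    if (is.null(basis)) {
      abort("the semiparametric family needs a `basis` (see spline_basis())")
    }
    stopifnot(inherits(basis, "spline_basis"))
  }
  k <- hf_arity(family, basis)
  if (length(rho) != k) {
    abort(sprintf("family '%s' takes %d parameter(s), got %d",
                  family, k, length(rho)))
  }
  if (family == "gompertz" && rho < 0) {
    warn("gompertz with p < 0 gives an *increasing* trajectory (wound growth)")
  }
  structure(
    list(family = family, rho = as.numeric(rho), t_max = t_max,
         basis = basis, as_printed = isTRUE(as_printed)),
    class = "healing_function"
  )
}

#' @export
print.healing_function <- function(x, ...) {
  cat("<healing_function> family:", x$family,
      " rho: [", paste(signif(x$rho, 4), collapse = ", "), "]",
      if (x$family %in% c("wendland0", "wendland1")) paste(" t_max:", x$t_max),
      "\n")
  invisible(x)
}

# Low-level evaluation on a numeric time vector. `B`/`dB` are the (shifted)
# basis matrix and its derivative, rows matching `t`; only the semiparametric
# family uses them. Returns the function value (not its log).
hf_value_raw <- function(family, rho, t, t_max = 100, B = NULL,
                         as_printed = FALSE) {
  switch(family,
    exponential = exp(-rho[1] * t),
    gompertz = exp(1 - exp(rho[1] * t)),
    linear = 1 + rho[1] * t,
    quadratic = 1 + rho[1] * t + rho[2] * t^2,
    square_root = 1 + rho[1] * t + rho[2] * sqrt(t),
    wendland0 = {
      s <- pmin(t / t_max, 1)
      (1 - s)^rho[1]
    },
    wendland1 = {
      s <- t / t_max
      if (as_printed) {
        (1 + (rho[1] + 1) * s) * (1 + s)^(rho[1] + 1)
      } else {
        sp <- pmin(s, 1)
        (1 + (rho[1] + 1) * sp) * (1 - sp)^(rho[1] + 1)
      }
    },
    semiparametric = 1 - drop(B %*% rho),
    log_linear = exp(1 + rho[1] * t),
    log_quadratic = exp(1 + rho[1] * t + rho[2] * t^2),
    log_square_root = exp(1 + rho[1] * t + rho[2] * sqrt(t)),
    abort(sprintf("unknown family '%s'", family))
  )
}

hf_deriv_raw <- function(family, rho, t, t_max = 100, dB = NULL,
                         as_printed = FALSE) {
  switch(family,
    exponential = -rho[1] * exp(-rho[1] * t),
    gompertz = -rho[1] * exp(rho[1] * t) * exp(1 - exp(rho[1] * t)),
    linear = rep_len(rho[1], length(t)),
    quadratic = rho[1] + 2 * rho[2] * t,
    square_root = rho[1] + rho[2] / (2 * sqrt(t)),
    wendland0 = {
      s <- t / t_max
      ifelse(s >= 1, 0, -rho[1] * (1 - pmin(s, 1))^(rho[1] - 1) / t_max)
    },
    wendland1 = {
      s <- t / t_max
      if (as_printed) {
        (rho[1] + 1) * (1 + s)^rho[1] * (2 + (rho[1] + 2) * s) / t_max
      } else {
        ifelse(s >= 1, 0,
               -(rho[1] + 1) * (rho[1] + 2) * s * (1 - pmin(s, 1))^rho[1] / t_max)
      }
    },
    semiparametric = -drop(dB %*% rho),
    log_linear = rho[1] * exp(1 + rho[1] * t),
    log_quadratic = (rho[1] + 2 * rho[2] * t) *
      exp(1 + rho[1] * t + rho[2] * t^2),
    log_square_root = (rho[1] + rho[2] / (2 * sqrt(t))) *
      exp(1 + rho[1] * t + rho[2] * sqrt(t)),
    abort(sprintf("unknown family '%s'", family))
  )
}

#' Evaluate a healing-rate function
#'
#' @param hf A [healing_function()].
#' @param t Non-negative time(s) in days.
#' @return Numeric vector `f(t; rho)`, same length as `t`. The Wendland
#'   families return exactly 0 for `t >= t_max`.
#' @export
hf_eval <- function(hf, t) {
  stopifnot(inherits(hf, "healing_function"))
  if (!is.numeric(t) || anyNA(t)) abort("`t` must be numeric without NA")
  if (any(t < 0)) abort("`t` must be non-negative")
  B <- if (hf$family == "semiparametric") sb_matrix(hf$basis, t) else NULL
  hf_value_raw(hf$family, hf$rho, t, hf$t_max, B, hf$as_printed)
}

#' Evaluate the time derivative of a healing-rate function
#'
#' The derivative is analytic for every family. The square-root families have
#' an unbounded derivative at `t = 0`, so evaluation exactly at 0 is a domain
#' error for them; rate estimands only ever use `t > 0`.
#'
#' @inheritParams hf_eval
#' @return Numeric vector `df/dt`, in 1/days.
#' @export
hf_deriv <- function(hf, t) {
  stopifnot(inherits(hf, "healing_function"))
  if (!is.numeric(t) || anyNA(t)) abort("`t` must be numeric without NA")
  if (any(t < 0)) abort("`t` must be non-negative")
  if (hf$family %in% c("square_root", "log_square_root") && any(t == 0)) {
    abort("the square-root derivative is singular at t = 0; use t > 0")
  }
  dB <- if (hf$family == "semiparametric") sb_matrix(hf$basis, t, deriv = 1L) else NULL
  hf_deriv_raw(hf$family, hf$rho, t, hf$t_max, dB, hf$as_printed)
}

#' B-spline basis for the semiparametric healing-rate function
#'
#' Builds a degree-`degree` B-spline basis with `n_knots` interior knots
#' spaced evenly over `time_range`. Each basis column is shifted by its value
#' at `t = 0` so that every `h_m(0) = 0`; this anchors the semiparametric
#' `f(t) = 1 - sum_m p_m h_m(t)` at `f(0) = 1` and makes the coefficients
#' identifiable against the model intercept.
#'
#' @param time_range Length-2 numeric, the closed interval the basis covers
#'   (typically `c(0, 70)` for a 70-day trial).
#' @param n_knots Number of interior knots, evenly spaced (default 5).
#' @param degree Spline degree (default 3, i.e. cubic).
#' @return An object of class `spline_basis` with `basis_count = n_knots +
#'   degree` columns.
#' @export
#' @examples
#' sb <- spline_basis(c(0, 70))
#' dim(sb_matrix(sb, c(0, 10, 35, 70)))
spline_basis <- function(time_range, n_knots = 5L, degree = 3L) {
  if (length(time_range) != 2L || diff(time_range) <= 0) {
    abort("`time_range` must be a nondegenerate increasing interval")
  }
  if (n_knots < 1L) abort("`n_knots` must be >= 1")
  lo <- time_range[1]; hi <- time_range[2]
  interior <- seq(lo, hi, length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  ord <- degree + 1L
  aknots <- c(rep(lo, ord), interior, rep(hi, ord))
  basis <- structure(
    list(degree = as.integer(degree), knots = interior,
         time_range = as.numeric(time_range), aknots = aknots,
         basis_count = as.integer(n_knots + degree)),
    class = "spline_basis"
  )
  basis$shift <- rep(0, basis$basis_count)
  t0 <- min(max(0, lo), hi)  # anchor point: t = 0, clamped into the range
  basis$shift <- drop(sb_matrix(basis, t0))
  basis
}

#' Evaluate a spline basis (or its derivative) at times `t`
#'
#' @param basis A [spline_basis()].
#' @param t Times within the basis `time_range`.
#' @param deriv Derivative order (0 or 1).
#' @return Matrix with `length(t)` rows and `basis_count` columns.
#' @export
sb_matrix <- function(basis, t, deriv = 0L) {
  stopifnot(inherits(basis, "spline_basis"))
  rng <- basis$time_range
  if (any(t < rng[1] - 1e-9 | t > rng[2] + 1e-9)) {
    abort(sprintf("t outside the basis time_range [%g, %g]", rng[1], rng[2]))
  }
  t <- pmin(pmax(t, rng[1]), rng[2])
  ord <- basis$degree + 1L
  X <- splines::splineDesign(basis$aknots, t, ord = ord,
                             derivs = rep(deriv, length(t)))
  X <- X[, -1L, drop = FALSE]  # drop the intercept column
  if (deriv == 0L) X <- sweep(X, 2L, basis$shift, "-")
  X
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("<spline_basis> degree", x$degree, "with", length(x$knots),
      "interior knots on [", x$time_range[1], ",", x$time_range[2], "] ->",
      x$basis_count, "columns\n")
  invisible(x)
}
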