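# Metropolis-within-Gibbs sampler for the hierarchical wound model.
#
# Parameterisation: log y_it = (mu - omega^2/2) + alpha_i + log f(t; rho_a)
# + e_it with alpha_i ~ N(0, tau^2), e ~ N(0, omega^2). For sampler geometry
# the patient effects are integrated out analytically: writing
# r_it = log y_it - log f + omega^2/2, each patient's vector r_i is
# N(mu 1, omega^2 I + tau^2 J), so the collapsed likelihood only needs the
# per-patient sufficient statistics (n_i, mean, within-patient SS). mu gets
# a conjugate normal update on the collapsed likelihood; tau, omega and the
# healing-rate parameters are updated by stepping-out slice sampling (rho
# along eigen-directions of its warmup covariance, which handles the strong
# collinearity of e.g. the t and sqrt(t) regressors). The alpha_i are drawn
# from their exact conditional at the end of each iteration for storage.
# f(t) <= 0 at any observed time gives a -Inf collapsed log-likelihood,
# which slice shrinkage rejects (soft positivity constraint).

# Univariate stepping-out slice sampler (Neal 2003). `logf` must be finite
# at x0.
slice_sample1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 30L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) abort("slice sampler started at a zero-density point")
  logy <- f0 - stats::rexp(1)
  u <- runif(1, 0, w)
  L <- max(x0 - u, lower)
  R <- min(L + w, upper)
  j <- floor(runif(1, 0, max_steps))
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > logy) {
    L <- max(L - w, lower); j <- j - 1
  }
  while (k > 0 && R < upper && logf(R) > logy) {
    R <- min(R + w, upper); k <- k - 1
  }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Internal data bundle for one fit.
mcmc_prepare_data <- function(data, family, t_max, basis) {
  ids <- as.character(data$patient_id)
  uid <- unique(ids)
  pid <- match(ids, uid)
  n_pat <- length(uid)
  arm_by_patient <- vapply(split(as.integer(data$arm), pid),
                           function(a) a[1], integer(1))
  ut <- sort(unique(data$day))
  idx_arm <- lapply(c(0L, 1L), function(a) which(data$arm == a))
  # per-arm local patient indexing for fast sufficient statistics
  arm_local <- lapply(idx_arm, function(idx) {
    pats <- unique(pid[idx])
    list(pats = pats,                      # global patient ids in this arm
         lpid = match(pid[idx], pats),     # obs -> local patient index
         n_i = tabulate(match(pid[idx], pats), length(pats)))
  })
  list(
    L = log(data$area_cm2),
    pid = pid, ids = uid, n_pat = n_pat,
    arm_pat = if (n_pat) arm_by_patient[as.character(seq_len(n_pat))] else integer(0),
    ut = ut, t_idx = match(data$day, ut),
    idx_arm = idx_arm, arm_local = arm_local,
    n_i = tabulate(pid, n_pat),
    B_ut = if (family == "semiparametric") sb_matrix(basis, ut) else NULL,
    n_obs = nrow(data)
  )
}

# log f at the unique times; NULL when any f <= 0 (rejection marker).
mcmc_logf_ut <- function(family, rho, ut, t_max, B_ut, as_printed = FALSE) {
  f <- hf_value_raw(family, rho, ut, t_max, B_ut, as_printed)
  if (any(!is.finite(f)) || any(f <= 0)) return(NULL)
  log(f)
}

# Collapsed log-likelihood from per-patient sufficient statistics of
# b = log y - log f: for each patient, r_i = b_i + omega^2/2 is
# N(mu 1, omega^2 I + tau^2 J).
collapsed_ll <- function(n_i, bbar, SS, mu, tau, omega) {
  v <- omega^2 + n_i * tau^2
  rbar <- bbar + omega^2 / 2
  sum(-0.5 * (n_i - 1) * log(omega^2) - 0.5 * log(v) -
        SS / (2 * omega^2) - n_i * (rbar - mu)^2 / (2 * v)) -
    0.5 * sum(n_i) * log(2 * pi)
}

# Per-patient stats of b over an index subset with local patient map.
arm_stats <- function(b, lpid, n_i) {
  sb <- as.numeric(rowsum(b, lpid, reorder = TRUE))
  sb2 <- as.numeric(rowsum(b^2, lpid, reorder = TRUE))
  bbar <- sb / n_i
  list(bbar = bbar, SS = sb2 - n_i * bbar^2)
}

run_chain <- function(prep, family, t_max, priors, n_iter, n_warmup, seed,
                      as_printed = FALSE, init = NULL,
                      slice_w = c(tau = 0.1, omega = 0.05, rho = 0.01)) {
  set.seed(as.integer(seed))
  n_obs <- prep$n_obs
  n_pat <- prep$n_pat
  k <- length(init$rho0)
  L <- prep$L

  mu <- init$mu; tau <- init$tau; omega <- init$omega
  rho <- list(`0` = init$rho0, `1` = init$rho1)

  # per-observation log f, maintained per arm
  logf_obs <- numeric(n_obs)
  has_obs <- n_obs > 0L
  if (has_obs) {
    for (a in c(0L, 1L)) {
      lf <- mcmc_logf_ut(family, rho[[a + 1L]], prep$ut, t_max, prep$B_ut,
                         as_printed)
      if (is.null(lf)) abort("initial rho gives f <= 0 at an observed time")
      idx <- prep$idx_arm[[a + 1L]]
      logf_obs[idx] <- lf[prep$t_idx[idx]]
    }
  }

  # slice directions for rho: identity during early warmup, then the
  # eigenvectors of the warmup covariance (scaled) per arm
  dirs <- lapply(1:2, function(i) list(V = diag(k), w = rep(slice_w[["rho"]], k)))
  adapt_at <- if (n_warmup >= 100L) n_warmup %/% 2L else Inf
  hist_rho <- if (is.finite(adapt_at)) {
    lapply(1:2, function(i) matrix(NA_real_, adapt_at, k))
  } else NULL

  total <- n_warmup + n_iter
  draws <- matrix(NA_real_, n_iter, 3L + 2L * k)
  zmat <- matrix(NA_real_, n_iter, n_pat)

  for (it in seq_len(total)) {
    if (has_obs) {
      # --- rho per arm: slice along direction set on collapsed likelihood ---
      for (a in c(0L, 1L)) {
        idx <- prep$idx_arm[[a + 1L]]
        al <- prep$arm_local[[a + 1L]]
        if (!length(idx)) {
          rho[[a + 1L]] <- rnorm(k, 0, priors$rho_sd)
          next
        }
        La <- L[idx]; ti <- prep$t_idx[idx]
        ll_rho <- function(rr) {
          lf <- mcmc_logf_ut(family, rr, prep$ut, t_max, prep$B_ut, as_printed)
          if (is.null(lf)) return(-Inf)
          st <- arm_stats(La - lf[ti], al$lpid, al$n_i)
          collapsed_ll(al$n_i, st$bbar, st$SS, mu, tau, omega) +
            sum(dnorm(rr, 0, priors$rho_sd, log = TRUE))
        }
        rr <- rho[[a + 1L]]
        D <- dirs[[a + 1L]]
        for (j in seq_len(k)) {
          v <- D$V[, j]
          rr <- rr + v * slice_sample1(0, function(s) ll_rho(rr + s * v),
                                       w = D$w[j])
        }
        rho[[a + 1L]] <- rr
        lf <- mcmc_logf_ut(family, rr, prep$ut, t_max, prep$B_ut, as_printed)
        logf_obs[idx] <- lf[ti]
        if (it <= adapt_at) hist_rho[[a + 1L]][it, ] <- rr
      }
      if (it == adapt_at) {
        for (a in 1:2) {
          Hr <- hist_rho[[a]][seq(max(1L, adapt_at %/% 2L), adapt_at), ,
                              drop = FALSE]
          C <- stats::cov(Hr)
          if (all(is.finite(C)) && all(diag(C) > 0)) {
            eg <- eigen(C, symmetric = TRUE)
            lam <- pmax(eg$values, max(eg$values) * 1e-8)
            dirs[[a]] <- list(V = eg$vectors, w = 3 * sqrt(lam))
          }
        }
      }

      # --- global per-patient stats of b = L - log f ---
      b <- L - logf_obs
      sbl <- as.numeric(rowsum(b, prep$pid, reorder = TRUE))
      sb2 <- as.numeric(rowsum(b^2, prep$pid, reorder = TRUE))
      bbar <- sbl / prep$n_i
      SS <- sb2 - prep$n_i * bbar^2

      # --- mu | rest (conjugate on collapsed likelihood) ---
      vv <- omega^2 + prep$n_i * tau^2
      prec <- 1 / priors$mu_sd^2 + sum(prep$n_i / vv)
      mm <- (priors$mu_mean / priors$mu_sd^2 +
               sum(prep$n_i * (bbar + omega^2 / 2) / vv)) / prec
      mu <- rnorm(1, mm, sqrt(1 / prec))

      # --- tau | rest (slice, collapsed) ---
      ll_tau <- function(tt) {
        if (tt < 0) return(-Inf)
        collapsed_ll(prep$n_i, bbar, SS, mu, tt, omega) +
          dnorm(tt, 0, priors$tau_sd, log = TRUE)
      }
      tau <- slice_sample1(tau, ll_tau, w = slice_w[["tau"]], lower = 0)

      # --- omega | rest (slice, collapsed; omega also shifts the mean) ---
      ll_omega <- function(om) {
        if (om <= 0) return(-Inf)
        collapsed_ll(prep$n_i, bbar, SS, mu, tau, om) +
          dnorm(om, 0, priors$omega_sd, log = TRUE)
      }
      omega <- slice_sample1(omega, ll_omega, w = slice_w[["omega"]],
                             lower = 1e-8)
    } else {
      # prior sampling
      mu <- rnorm(1, priors$mu_mean, priors$mu_sd)
      tau <- abs(rnorm(1, 0, priors$tau_sd))
      omega <- abs(rnorm(1, 0, priors$omega_sd))
      rho[[1L]] <- rnorm(k, 0, priors$rho_sd)
      rho[[2L]] <- rnorm(k, 0, priors$rho_sd)
    }

    if (it > n_warmup) {
      kk <- it - n_warmup
      draws[kk, ] <- c(mu, tau, omega, rho[[1L]], rho[[2L]])
      # --- alpha_i (as z = alpha/tau) | rest: exact conditional ---
      if (has_obs) {
        vz <- 1 / (1 + prep$n_i * tau^2 / omega^2)
        mz <- vz * (tau / omega^2) * prep$n_i * (bbar + omega^2 / 2 - mu)
        zmat[kk, ] <- rnorm(n_pat, mz, sqrt(vz))
      } else {
        zmat[kk, ] <- rnorm(n_pat)
      }
    }
  }
  colnames(draws) <- c("mu", "tau", "omega",
                       paste0("rho0_", seq_len(k)), paste0("rho1_", seq_len(k)))
  list(draws = draws, z = zmat)
}

# Find a valid starting point: f > 0 at every observed time in both arms.
mcmc_init <- function(prep, family, t_max, priors, basis, max_tries = 100L) {
  k <- hf_arity(family, basis)
  if (prep$n_obs > 0L) {
    first_idx <- which(prep$t_idx == 1L)
    mu0 <- log(mean(exp(prep$L[if (length(first_idx)) first_idx else seq_len(prep$n_obs)])))
  } else {
    mu0 <- priors$mu_mean
  }
  rho_start <- switch(family,
    exponential = 0.01, gompertz = 0.01,
    wendland0 = 1, wendland1 = 1,
    semiparametric = rep(0, k),
    rep(-0.001, k)
  )
  rho_start <- rep_len(rho_start, k)
  for (try in seq_len(max_tries)) {
    r0 <- if (try == 1L) rho_start else rho_start * runif(k, 0, 1)
    ok <- prep$n_obs == 0L ||
      !is.null(mcmc_logf_ut(family, r0, prep$ut, t_max, prep$B_ut))
    if (ok) {
      return(list(mu = mu0, tau = 0.5 * priors$tau_sd,
                  omega = 0.5 * priors$omega_sd,
                  rho0 = r0, rho1 = r0, z = rep(0, prep$n_pat)))
    }
  }
  abort("no valid starting point with f > 0 at all observed times in 100 attempts")
}
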