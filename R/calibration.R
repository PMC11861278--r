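#' Calibration configuration
#'
#' Controls which parameters are fitted, how the initial state is built from
#' the first observation, which compartments constitute a reported "case",
#' and the likelihood family. The defaults mirror the published workflow:
#' free parameters (beta1, beta2, gamma2), all other rates fixed, cases
#' read as P + D.
#'
#' @param params fixed [model_parameters()] supplying every non-free rate
#'   (free entries are used as fallback/truth references only).
#' @param free character vector of free parameter names.
#' @param lower,upper named (or positionally matched) optimizer bounds for
#'   the free parameters; default (1e-6, 1] for each rate.
#' @param observable `"PD"` (cases = P + D), `"D"`, or `"PDMC"`
#'   (P + D + M + C; required if `gamma2` is to be identifiable from the
#'   series, as `gamma2` reaches P + D only through the weak relapse loop).
#' @param noise `"gaussian"` (constant variance, profiled analytically) or
#'   `"poisson"`.
#' @param n0 total population behind the series (persons).
#' @param pd_split fraction of first-year cases assigned to P (rest to D).
#' @param b_frac initial saboteur fraction of the total population.
#' @param n_starts number of multi-start optimizer launches.
#' @param seed seed for the start scatter.
#' @param maxit per-start optimizer iteration cap.
#' @param rtol integration tolerance used inside the likelihood.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(params = spain_parameters(ref_pop = 4.7e7),
                       free = c("beta1", "beta2", "gamma2"),
                       lower = rep(1e-6, length(free)),
                       upper = rep(1, length(free)),
                       observable = c("PD", "D", "PDMC"),
                       noise = c("gaussian", "poisson"),
                       n0 = 4.7e7, pd_split = 0.5, b_frac = 0.01,
                       n_starts = 8, seed = 1, maxit = 300, rtol = 1e-8) {
  observable <- match.arg(observable)
  noise <- match.arg(noise)
  bad <- setdiff(free, PARAM_NAMES)
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  lower <- stats::setNames(as.numeric(lower), free)
  upper <- stats::setNames(as.numeric(upper), free)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("optimizer bounds must be finite")
  }
  if (any(lower > upper)) stop("lower bounds exceed upper bounds")
  structure(list(params = params, free = free, lower = lower, upper = upper,
                 observable = observable, noise = noise, n0 = n0,
                 pd_split = pd_split, b_frac = b_frac, n_starts = n_starts,
                 seed = seed, maxit = maxit, rtol = rtol),
            class = "fit_config")
}

# Initial state rule: total population n0; first-year cases split between
# P and D; saboteurs a fixed fraction of n0; M = C = R = 0; S the remainder.
fit_initial_state <- function(series, config) {
  cases0 <- series$cases[1]
  P0 <- config$pd_split * cases0
  D0 <- (1 - config$pd_split) * cases0
  B0 <- config$b_frac * config$n0
  S0 <- config$n0 - P0 - D0 - B0
  if (S0 < 0) stop("initial cases and saboteur fraction exceed total population")
  state_vector(S = S0, B = B0, P = P0, D = D0)
}

predicted_cases <- function(free_values, series, config) {
  p <- config$params
  if (length(config$free)) {
    repl <- stats::setNames(as.list(as.numeric(free_values)), config$free)
    p <- do.call(update_parameters, c(list(p), repl))
  }
  init <- fit_initial_state(series, config)
  times <- series$year - series$year[1]
  traj <- simulate_depression(p, init, times, rtol = config$rtol,
                              atol_scale = 1e-10)
  observable_map(traj, config$observable)
}

#' Negative log-likelihood of a prevalence series
#'
#' Integrates the model from the configured initial state, maps states to
#' predicted yearly cases, and evaluates the negative log-likelihood. Under
#' the Gaussian model the constant observation variance is profiled out in
#' closed form (sigma-hat^2 = RSS/n, floored at (1e-8 mean|cases|)^2 so a
#' perfect fit returns a finite degenerate floor); under the Poisson model
#' the counts enter an ordinary Poisson likelihood. Integration failures
#' return a large-but-finite penalty flagged via the `"failed"` attribute.
#'
#' @param free_values numeric values for `config$free`, within bounds.
#' @param series a `prevalence_series` (>= 2 observations; variance
#'   profiling is undefined for a single year).
#' @param config a [fit_config()].
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(free_values, series, config) {
  n <- nrow(series)
  if (n < 2) stop("variance profiling needs at least 2 observations")
  pred <- tryCatch(predicted_cases(free_values, series, config),
                   error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred))) {
    return(structure(1e10, failed = TRUE))
  }
  obs <- series$cases
  if (config$noise == "gaussian") {
    rss <- sum((obs - pred)^2)
    floor_var <- (1e-8 * mean(abs(obs)))^2
    s2 <- max(rss / n, floor_var)
    n / 2 * log(2 * pi * s2) + n / 2
  } else {
    lam <- pmax(pred, 1e-12)
    sum(lam - obs * log(lam) + lgamma(obs + 1))
  }
}

# Smooth objective actually minimized: for the Gaussian family a scaled RSS
# (monotone in the profiled NLL but free of the log's vanishing-gradient
# plateau and RSS->0 blow-up); for Poisson the NLL itself.
fit_objective <- function(free_values, series, config, scale2) {
  if (config$noise == "gaussian") {
    pred <- tryCatch(predicted_cases(free_values, series, config),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e10)
    sum((series$cases - pred)^2) / scale2
  } else {
    as.numeric(negative_log_likelihood(free_values, series, config))
  }
}

#' Maximum-likelihood fit of the depression model
#'
#' Bounded multi-start local optimization (`L-BFGS-B`) of the likelihood
#' over the free parameters, with starts from a seeded Latin-hypercube
#' scatter within the bounds (plus the fixed parameter values as one start
#' when they fall inside). The best converged start is returned with
#' convergence diagnostics and R0 at the optimum.
#'
#' @param series a `prevalence_series` with >= 4 observations.
#' @param config a [fit_config()].
#' @return List of class `depression_fit`: `estimates`, `nll`, `converged`,
#'   `n_converged_starts`, `r0`, `free`, `config`, `optim` (best raw result).
#' @export
fit_mle <- function(series, config) {
  if (nrow(series) < 4) stop("need at least 4 observations to fit")
  if (!length(config$free)) {
    nll <- negative_log_likelihood(numeric(0), series, config)
    return(structure(list(estimates = stats::setNames(numeric(0), character(0)),
                          nll = nll, converged = TRUE, n_converged_starts = 0L,
                          r0 = r0_closed_form(config$params),
                          free = character(0), config = config, optim = NULL),
                     class = "depression_fit"))
  }
  k <- length(config$free)
  scale2 <- mean(series$cases)^2
  lh <- withr::with_seed(config$seed, lhs::randomLHS(config$n_starts, k))
  starts <- lapply(seq_len(config$n_starts), function(i) {
    config$lower + as.numeric(lh[i, ]) * (config$upper - config$lower)
  })
  centre <- unlist(config$params[config$free])
  if (all(centre >= config$lower & centre <= config$upper)) {
    starts <- c(starts, list(centre))
  }
  best <- NULL
  n_conv <- 0L
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, fit_objective, series = series, config = config,
                   scale2 = scale2, method = "L-BFGS-B",
                   lower = config$lower, upper = config$upper,
                   control = list(maxit = config$maxit, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(estimates = stats::setNames(rep(NA_real_, k),
                                                      config$free),
                          nll = NA_real_, converged = FALSE,
                          n_converged_starts = 0L, r0 = NA_real_,
                          free = config$free, config = config, optim = NULL),
                     class = "depression_fit"))
  }
  est <- stats::setNames(as.numeric(best$par), config$free)
  repl <- stats::setNames(as.list(est), config$free)
  p_hat <- do.call(update_parameters, c(list(config$params), repl))
  structure(list(estimates = est,
                 nll = as.numeric(negative_log_likelihood(est, series, config)),
                 converged = n_conv > 0L,
                 n_converged_starts = n_conv,
                 r0 = tryCatch(r0_closed_form(p_hat), error = function(e) NA_real_),
                 free = config$free, config = config, optim = best),
            class = "depression_fit")
}

#' Wald 95% confidence intervals for a converged fit
#'
#' Observed information at the optimum, inverted into standard errors;
#' intervals estimate +/- 1.96 SE, truncated at the optimizer bounds. For
#' the Gaussian family the information is the Gauss-Newton form
#' J'J / sigma-hat^2 built from a central-finite-difference residual
#' Jacobian (positive semi-definite by construction, and far less sensitive
#' to integrator noise than differencing the profiled log-likelihood twice);
#' for the Poisson family a numerical Hessian of the NLL is used. Parameters
#' whose information is not invertible get `NA` intervals rather than a
#' fabricated width.
#'
#' @param fit a converged [fit_mle()] result.
#' @param series,config the data and configuration used for the fit.
#' @return The fit, extended with `se`, `ci_lower`, `ci_upper` and the
#'   Hessian.
#' @export
wald_confidence_intervals <- function(fit, series, config) {
  if (!isTRUE(fit$converged) || !length(fit$estimates)) {
    stop("Wald intervals need a converged fit with free parameters")
  }
  if (config$noise == "gaussian") {
    n <- nrow(series)
    k <- length(fit$estimates)
    pred0 <- predicted_cases(fit$estimates, series, config)
    rss <- sum((series$cases - pred0)^2)
    s2 <- max(rss / n, (1e-8 * mean(abs(series$cases)))^2)
    Jr <- matrix(0, n, k)
    for (j in seq_len(k)) {
      h <- 1e-5 * max(abs(fit$estimates[j]), 1e-4)
      up <- fit$estimates; up[j] <- up[j] + h
      dn <- fit$estimates; dn[j] <- dn[j] - h
      Jr[, j] <- (predicted_cases(up, series, config) -
                    predicted_cases(dn, series, config)) / (2 * h)
    }
    H <- crossprod(Jr) / s2
  } else {
    H <- stats::optimHess(fit$estimates, function(th) {
      as.numeric(negative_log_likelihood(th, series, config))
    })
  }
  ci <- wald_from_hessian(fit$estimates, H, config$lower, config$upper)
  fit$se <- ci$se
  fit$ci_lower <- ci$lower
  fit$ci_upper <- ci$upper
  fit$hessian <- H
  fit
}

# Shared Wald machinery: estimates + observed-information Hessian -> SEs and
# bound-truncated 95% intervals; non-positive-definite information yields NA.
wald_from_hessian <- function(estimates, hessian, lower = -Inf, upper = Inf) {
  k <- length(estimates)
  se <- rep(NA_real_, k)
  cov <- tryCatch(solve(hessian), error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    ok <- is.finite(d) & d > 0
    se[ok] <- sqrt(d[ok])
  }
  lower_ci <- pmax(estimates - 1.96 * se, rep(lower, length.out = k))
  upper_ci <- pmin(estimates + 1.96 * se, rep(upper, length.out = k))
  list(se = stats::setNames(se, names(estimates)),
       lower = stats::setNames(lower_ci, names(estimates)),
       upper = stats::setNames(upper_ci, names(estimates)))
}

#' @export
print.depression_fit <- function(x, ...) {
  cat("Depression-model ML fit (", length(x$free), " free parameter(s))\n",
      sep = "")
  if (length(x$estimates)) {
    tab <- data.frame(estimate = x$estimates)
    if (!is.null(x$se)) {
      tab$se <- x$se; tab$ci95_lower <- x$ci_lower; tab$ci95_upper <- x$ci_upper
    }
    print(tab)
  }
  cat("NLL:", x$nll, " converged:", x$converged,
      " R0 at estimate:", x$r0, "\n")
  invisible(x)
}

#' Flat CSV export of a fit (estimate / SE / CI rows)
#'
#' @param fit a [fit_mle()] result, ideally after
#'   [wald_confidence_intervals()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_fit_csv <- function(fit, path) {
  df <- data.frame(parameter = fit$free,
                   estimate = signif(fit$estimates, 12),
                   se = if (is.null(fit$se)) NA_real_ else signif(fit$se, 12),
                   ci95_lower = if (is.null(fit$ci_lower)) NA_real_ else signif(fit$ci_lower, 12),
                   ci95_upper = if (is.null(fit$ci_upper)) NA_real_ else signif(fit$ci_upper, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
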