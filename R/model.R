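#' Right-hand side of the saboteur-depression model
#'
#' Evaluates the seven time derivatives of the compartmental model. Contact
#' processes are frequency dependent (divided by the total population N):
#' susceptibles are recruited into the saboteur class by contact with
#' saboteurs (`beta1 B S / N`), into primary depression by contact with the
#' secondary depressed (`beta2 D S / N`), and primary-depressed individuals
#' are pushed into secondary depression by saboteur contact
#' (`lambda1 B P / N`). The componentwise sum of the derivative is exactly
#' `Lambda - mu N - sigma D`: internal transfers cancel.
#'
#' @param state numeric length-7 state (S, B, P, D, M, C, R); non-negative,
#'   with positive total.
#' @param params a [model_parameters()] object.
#' @return Named numeric vector of the seven derivatives (per year).
#' @export
depression_rhs <- function(state, params) {
  depression_rhs_controlled(state, params, c(0, 0, 0))
}

#' Controlled right-hand side (three treatment controls)
#'
#' Extends [depression_rhs()] with bounded controls: `u1` adds to the
#' non-pharmacological uptake `psi1` (P -> M), `u2` to the pharmacological
#' uptake `psi2` (D -> C), and `u3` to the pharmacological recovery `gamma2`
#' (C -> R). With `controls = c(0,0,0)` the controlled system reduces exactly
#' to the uncontrolled one.
#'
#' @inheritParams depression_rhs
#' @param controls numeric length 3, `c(u1, u2, u3)`.
#' @return Named numeric vector of the seven derivatives.
#' @export
depression_rhs_controlled <- function(state, params, controls) {
  x <- as_state(state)
  N <- sum(x)
  if (!is.finite(N) || N <= 0) {
    stop("total population must be positive: frequency-dependent contact ",
         "terms are undefined at N = ", N)
  }
  u <- as.numeric(controls)
  if (length(u) != 3) stop("controls must have 3 components (u1, u2, u3)")
  S <- x[[1]]; B <- x[[2]]; P <- x[[3]]; D <- x[[4]]
  M <- x[[5]]; C <- x[[6]]; R <- x[[7]]
  sab_contact <- params$beta1 * B * S / N
  dep_contact <- params$beta2 * D * S / N
  aggravation <- params$lambda1 * B * P / N
  c(S = params$Lambda - sab_contact - dep_contact - params$mu * S,
    B = sab_contact - params$mu * B,
    P = dep_contact - aggravation -
      (params$lambda2 + params$mu + params$psi1 + u[1]) * P,
    D = aggravation + params$lambda2 * P + params$omega * R -
      (params$psi2 + u[2] + params$mu + params$sigma) * D,
    M = (params$psi1 + u[1]) * P - (params$gamma1 + params$mu) * M,
    C = (params$psi2 + u[2]) * D - (params$gamma2 + u[3] + params$mu) * C,
    R = params$gamma1 * M + (params$gamma2 + u[3]) * C -
      (params$mu + params$omega) * R)
}

#' Jacobian of the (controlled) model right-hand side
#'
#' Exact analytic 7x7 Jacobian, differentiating the frequency-dependent
#' contact terms through both their numerators and the total N. A central
#' finite-difference variant (`method = "fd"`, relative step 1e-7) is kept as
#' an independent cross-check.
#'
#' @inheritParams depression_rhs_controlled
#' @param method `"analytic"` (default) or `"fd"`.
#' @return 7x7 matrix, rows = equations, columns = states.
#' @export
model_jacobian <- function(state, params, controls = c(0, 0, 0),
                           method = c("analytic", "fd")) {
  method <- match.arg(method)
  x <- as_state(state)
  N <- sum(x)
  if (!is.finite(N) || N <= 0) stop("Jacobian undefined at N = ", N)
  if (method == "fd") {
    J <- matrix(0, 7, 7, dimnames = list(COMPARTMENTS, COMPARTMENTS))
    scale <- max(abs(x), N)
    for (j in 1:7) {
      h <- 1e-7 * max(abs(x[j]), 1e-3 * scale)
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      J[, j] <- (depression_rhs_controlled(xp, params, controls) -
                   depression_rhs_controlled(xm, params, controls)) / (2 * h)
    }
    return(J)
  }
  S <- x[[1]]; B <- x[[2]]; P <- x[[3]]; D <- x[[4]]
  u <- as.numeric(controls)
  # gradient of a bilinear frequency term  c * a * b / N  w.r.t. all states:
  # (c/N) * (b e_a + a e_b) - c a b / N^2
  bilinear_grad <- function(coef, ia, ib, a, b) {
    g <- rep(-coef * a * b / N^2, 7)
    g[ia] <- g[ia] + coef * b / N
    g[ib] <- g[ib] + coef * a / N
    g
  }
  dT1 <- bilinear_grad(params$beta1, 1, 2, S, B)    # beta1 B S / N
  dT2 <- bilinear_grad(params$beta2, 1, 4, S, D)    # beta2 D S / N
  dT3 <- bilinear_grad(params$lambda1, 3, 2, P, B)  # lambda1 B P / N
  e <- function(i) { v <- numeric(7); v[i] <- 1; v }
  J <- rbind(
    S = -dT1 - dT2 - params$mu * e(1),
    B = dT1 - params$mu * e(2),
    P = dT2 - dT3 - (params$lambda2 + params$mu + params$psi1 + u[1]) * e(3),
    D = dT3 + params$lambda2 * e(3) + params$omega * e(7) -
      (params$psi2 + u[2] + params$mu + params$sigma) * e(4),
    M = (params$psi1 + u[1]) * e(3) - (params$gamma1 + params$mu) * e(5),
    C = (params$psi2 + u[2]) * e(4) - (params$gamma2 + u[3] + params$mu) * e(6),
    R = params$gamma1 * e(5) + (params$gamma2 + u[3]) * e(6) -
      (params$mu + params$omega) * e(7))
  colnames(J) <- COMPARTMENTS
  J
}

#' Integrate the model over a time grid
#'
#' Adaptive integration (deSolve `lsoda`, relative tolerance 1e-8, absolute
#' 1e-10 scaled to the population) of the uncontrolled or controlled system.
#' Controls may be a constant length-3 vector, a function of time returning
#' length 3, or a matrix/data.frame with columns (time, u1, u2, u3) that is
#' linearly interpolated. Negative undershoots beyond the solver tolerance
#' raise an error; smaller ones are clamped to zero in the returned output
#' only.
#'
#' @param params a [model_parameters()] object.
#' @param init non-negative initial state (7 components).
#' @param times strictly increasing numeric grid (years).
#' @param controls `NULL`, length-3 numeric, `function(t)`, or a 4-column
#'   time-indexed table.
#' @param rtol,atol_scale integration tolerances; the absolute tolerance is
#'   `atol_scale * max(1, N0)`.
#' @return A `depression_trajectory`: data.frame with columns
#'   `time, S, B, P, D, M, C, R, N`.
#' @export
simulate_depression <- function(params, init, times, controls = NULL,
                                rtol = 1e-8, atol_scale = 1e-10) {
  init <- as_state(init)
  if (any(init < 0)) stop("initial state must be non-negative")
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("'times' must be a strictly increasing grid with at least 2 points")
  }
  ufun <- control_schedule(controls)
  deriv <- function(t, y, parms) {
    list(depression_rhs_controlled(y, params, ufun(t)))
  }
  atol <- atol_scale * max(1, sum(init))
  sol <- deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("integrator failed to meet tolerances (istate = ",
         attr(sol, "istate")[1], "); no truncated trajectory is returned")
  }
  out <- as.data.frame(sol)
  names(out) <- c("time", COMPARTMENTS)
  states <- as.matrix(out[COMPARTMENTS])
  floor_tol <- 1e-8 * max(1, sum(init))
  if (any(states < -floor_tol)) {
    stop("integration produced a negative compartment beyond tolerance (min = ",
         format(min(states)), ")")
  }
  states[states < 0] <- 0
  out[COMPARTMENTS] <- states
  out$N <- rowSums(states)
  class(out) <- c("depression_trajectory", "data.frame")
  out
}

# Normalise the accepted control specifications to a function of time.
control_schedule <- function(controls) {
  if (is.null(controls)) return(function(t) c(0, 0, 0))
  if (is.function(controls)) return(controls)
  if (is.numeric(controls) && length(controls) == 3) {
    u <- as.numeric(controls)
    return(function(t) u)
  }
  tab <- as.data.frame(controls)
  if (ncol(tab) != 4) {
    stop("tabular controls need 4 columns: time, u1, u2, u3")
  }
  f1 <- stats::approxfun(tab[[1]], tab[[2]], rule = 2)
  f2 <- stats::approxfun(tab[[1]], tab[[3]], rule = 2)
  f3 <- stats::approxfun(tab[[1]], tab[[4]], rule = 2)
  function(t) c(f1(t), f2(t), f3(t))
}

#' Fixed-step classical Runge-Kutta integration
#'
#' Reference fourth-order integrator on a uniform grid, used as the
#' independent cross-check for the adaptive solver and as the workhorse of
#' the forward-backward sweep. Time-varying controls are taken at the node,
#' midpoint (average of adjacent nodes) and next node, the standard treatment
#' for gridded control schedules.
#'
#' @inheritParams simulate_depression
#' @param times uniform, strictly increasing grid.
#' @return Matrix of states, one row per grid time.
#' @export
rk4_integrate <- function(params, init, times, controls = NULL) {
  ufun <- control_schedule(controls)
  n <- length(times)
  out <- matrix(0, n, 7, dimnames = list(NULL, COMPARTMENTS))
  x <- as.numeric(as_state(init))
  out[1, ] <- x
  for (i in seq_len(n - 1)) {
    h <- times[i + 1] - times[i]
    tm <- times[i] + h / 2
    u0 <- ufun(times[i]); um <- ufun(tm); u1 <- ufun(times[i + 1])
    k1 <- depression_rhs_controlled(x, params, u0)
    k2 <- depression_rhs_controlled(x + h / 2 * k1, params, um)
    k3 <- depression_rhs_controlled(x + h / 2 * k2, params, um)
    k4 <- depression_rhs_controlled(x + h * k3, params, u1)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- x
  }
  out
}

#' Write / read a trajectory as CSV
#'
#' Plain UTF-8 CSV with header `time,S,B,P,D,M,C,R`, '.' decimal separator,
#' 12 significant digits.
#'
#' @param trajectory a `depression_trajectory` (or any data.frame with those
#'   columns).
#' @param path output file.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a `depression_trajectory`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  cols <- c("time", COMPARTMENTS)
  stopifnot(all(cols %in% names(trajectory)))
  df <- as.data.frame(trajectory)[cols]
  df[] <- lapply(df, function(v) signif(v, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  cols <- c("time", COMPARTMENTS)
  if (!all(cols %in% names(df))) {
    stop("trajectory CSV must have header time,S,B,P,D,M,C,R")
  }
  df <- df[cols]
  df$N <- rowSums(df[COMPARTMENTS])
  class(df) <- c("depression_trajectory", "data.frame")
  df
}
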