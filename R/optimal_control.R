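#' Weights and bounds of the control objective
#'
#' The running cost is W1 P + W2 D + W3 M + W4 C + (W5 u1^2 + W6 u2^2 +
#' W7 u3^2)/2; defaults are the published simulation weights (state costs 1,
#' control costs 15/40/55) with box bounds [0, 1] on each control.
#'
#' @param W1,W2,W3,W4 non-negative state-cost weights on P, D, M, C.
#' @param W5,W6,W7 strictly positive quadratic control-cost weights.
#' @param lower,upper length-3 control bounds (a_i <= b_i).
#' @return List of class `control_weights`.
#' @export
control_weights <- function(W1 = 1, W2 = 1, W3 = 1, W4 = 1,
                            W5 = 15, W6 = 40, W7 = 55,
                            lower = c(0, 0, 0), upper = c(1, 1, 1)) {
  w <- c(W1, W2, W3, W4, W5, W6, W7)
  if (any(w < 0)) stop("weights must be non-negative")
  if (any(c(W5, W6, W7) <= 0)) stop("control-cost weights W5..W7 must be positive")
  if (length(lower) != 3 || length(upper) != 3 || any(lower > upper)) {
    stop("control bounds must be length 3 with lower <= upper")
  }
  structure(list(W1 = W1, W2 = W2, W3 = W3, W4 = W4,
                 W5 = W5, W6 = W6, W7 = W7,
                 lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "control_weights")
}

#' Forward-backward sweep configuration
#'
#' @param t_f horizon in years.
#' @param n_grid number of uniform grid points (nodes).
#' @param tol convergence tolerance on the relative sup-norm control change.
#' @param max_iter iteration cap.
#' @param relax relaxation factor in (0, 1]: new = (1-relax) old +
#'   relax update.
#' @param mask logical length 3: which controls are active (strategy mask);
#'   inactive controls are held at 0.
#' @return List of class `oc_config`.
#' @export
oc_config <- function(t_f = 15, n_grid = 1501, tol = 1e-4, max_iter = 500,
                      relax = 0.5, mask = c(TRUE, TRUE, TRUE)) {
  if (t_f <= 0) stop("horizon must be positive")
  if (tol <= 0) stop("tolerance must be positive")
  if (relax <= 0 || relax > 1) stop("relaxation factor must lie in (0, 1]")
  if (length(mask) != 3) stop("mask must have 3 components")
  structure(list(t_f = t_f, n_grid = as.integer(n_grid), tol = tol,
                 max_iter = as.integer(max_iter), relax = relax,
                 mask = as.logical(mask)),
            class = "oc_config")
}

#' Objective functional J
#'
#' Composite trapezoidal integral of the running cost over the trajectory
#' grid.
#'
#' @param trajectory a `depression_trajectory` (or data.frame with `time`,
#'   `P`, `D`, `M`, `C`).
#' @param controls matrix/data.frame with columns u1, u2, u3 on the same
#'   grid.
#' @param weights a [control_weights()].
#' @return Scalar J.
#' @export
objective_value <- function(trajectory, controls, weights) {
  u <- as.matrix(as.data.frame(controls))
  if (nrow(u) != nrow(trajectory)) {
    stop("trajectory and controls must share one grid (",
         nrow(trajectory), " vs ", nrow(u), " rows)")
  }
  integrand <- weights$W1 * trajectory$P + weights$W2 * trajectory$D +
    weights$W3 * trajectory$M + weights$W4 * trajectory$C +
    0.5 * (weights$W5 * u[, 1]^2 + weights$W6 * u[, 2]^2 +
             weights$W7 * u[, 3]^2)
  pracma::trapz(trajectory$time, integrand)
}

#' Hamiltonian of the control problem
#'
#' Running cost (Lagrangian) plus the adjoint-weighted controlled dynamics
#' sum(Lambda_i dx_i/dt).
#'
#' @param state length-7 state.
#' @param adjoint length-7 adjoint values (Lambda_1..Lambda_7).
#' @param controls length-3 controls.
#' @param params a [model_parameters()].
#' @param weights a [control_weights()].
#' @return Scalar H.
#' @export
oc_hamiltonian <- function(state, adjoint, controls, params, weights) {
  x <- as_state(state)
  u <- as.numeric(controls)
  L <- weights$W1 * x[[3]] + weights$W2 * x[[4]] + weights$W3 * x[[5]] +
    weights$W4 * x[[6]] +
    0.5 * (weights$W5 * u[1]^2 + weights$W6 * u[2]^2 + weights$W7 * u[3]^2)
  L + sum(as.numeric(adjoint) * depression_rhs_controlled(x, params, u))
}

#' Adjoint system right-hand side
#'
#' dLambda/dt = -dH/dx, computed exactly as the negative transpose-Jacobian
#' product of the controlled dynamics plus the state-cost gradient
#' (0, 0, W1, W2, W3, W4, 0). This is the gradient of the implemented
#' Hamiltonian, the package's source of truth for the adjoints; the
#' published printed adjoint expressions are available separately as
#' [adjoint_rhs_printed()] for cross-checking.
#'
#' @inheritParams oc_hamiltonian
#' @return Length-7 derivative of the adjoint variables.
#' @export
adjoint_rhs <- function(state, adjoint, controls, params, weights) {
  J <- model_jacobian(state, params, controls)
  gradL <- c(0, 0, weights$W1, weights$W2, weights$W3, weights$W4, 0)
  -(as.numeric(crossprod(J, as.numeric(adjoint))) + gradL)
}

#' Printed adjoint expressions (cross-check only)
#'
#' Verbatim transcription of the published adjoint ODEs. Several of their
#' blocks (the repeated transmission terms in the M, C, R rows) do not
#' follow from differentiating the stated Hamiltonian; this function exists
#' so the discrepancy against [adjoint_rhs()] can be measured and logged,
#' not as the solver's adjoint.
#'
#' @inheritParams oc_hamiltonian
#' @return Length-7 derivative vector.
#' @export
adjoint_rhs_printed <- function(state, adjoint, controls, params, weights) {
  x <- as_state(state)
  S <- x[[1]]; B <- x[[2]]; P <- x[[3]]; D <- x[[4]]
  N <- sum(x)
  L <- as.numeric(adjoint)
  u <- as.numeric(controls)
  with(params, c(
    (beta1 * B / N^2 * (N - S)) * (L[1] - L[2]) +
      (beta2 * D / N^2 * (N - S)) * (L[1] - L[3]) -
      lambda1 * B * P / N^2 * (L[3] - L[4]) + L[1] * mu,
    (beta1 * S / N^2 * (N - B)) * (L[1] - L[2]) +
      (lambda1 * P / N^2 * (N - B)) * (L[3] - L[4]) -
      beta2 * D * S / N^2 * (L[1] - L[3]) + L[2] * mu,
    beta1 * B * S / N^2 * (L[1] - L[2]) -
      beta2 * D * S / N^2 * (L[1] - L[3]) +
      lambda2 * (L[3] - L[4]) -
      (lambda1 * B / N^2 * (N - P)) * (L[3] - L[4]) +
      (psi1 + u[1]) * (L[3] - L[5]) + mu * L[3] - weights$W1,
    beta1 * B * S / N^2 * (L[1] - L[2]) +
      (beta2 * S / N^2 * (N - D)) * (L[1] - L[3]) -
      lambda1 * B * P / N^2 * (L[3] - L[4]) +
      (psi2 + u[2]) * (L[4] - L[5]) + (mu + sigma) * L[4] - weights$W2,
    beta1 * B * S / N^2 * (L[1] - L[2]) -
      beta2 * D * S / N^2 * (L[1] - L[3]) -
      lambda1 * B * P / N^2 * (L[3] - L[4]) +
      gamma1 * (L[5] - L[7]) + mu * L[5] - weights$W3,
    beta1 * B * S / N^2 * (L[1] - L[2]) -
      beta2 * D * S / N^2 * (L[1] - L[3]) -
      lambda1 * B * P / N^2 * (L[3] - L[4]) +
      (gamma2 + u[3]) * (L[6] - L[7]) + mu * L[6] - weights$W4,
    beta1 * B * S / N^2 * (L[1] - L[2]) -
      beta2 * D * S / N^2 * (L[1] - L[3]) -
      lambda1 * B * P / N^2 * (L[3] - L[4]) +
      mu * L[7] + omega * (L[7] - L[4])))
}

#' Pointwise optimal-control update (projected stationarity condition)
#'
#' The Hamiltonian is quadratic in each control, so the unconstrained
#' minimizers are u1 = (Lambda_3 - Lambda_5) P / W5,
#' u2 = (Lambda_4 - Lambda_6) D / W6, u3 = (Lambda_6 - Lambda_7) C / W7,
#' projected onto the box bounds; controls inactive under the strategy mask
#' are forced to 0.
#'
#' @inheritParams oc_hamiltonian
#' @param mask logical length 3 of active controls.
#' @return Length-3 control vector within bounds.
#' @export
optimal_control_update <- function(state, adjoint, weights,
                                   mask = c(TRUE, TRUE, TRUE)) {
  x <- as_state(state)
  L <- as.numeric(adjoint)
  raw <- c((L[3] - L[5]) * x[[3]] / weights$W5,
           (L[4] - L[6]) * x[[4]] / weights$W6,
           (L[6] - L[7]) * x[[6]] / weights$W7)
  u <- pmin(pmax(raw, weights$lower), weights$upper)
  u[!mask] <- 0
  u
}

#' Forward-backward sweep solver
#'
#' Iterates (i) forward fixed-step RK4 integration of the controlled state
#' from the initial condition, (ii) backward RK4 integration of the adjoint
#' system from the transversality condition Lambda(t_f) = 0, (iii) the
#' projected control update with relaxation, until the relative sup-norm
#' control change drops below the tolerance or the iteration cap is hit
#' (non-convergence is flagged, the last iterate returned).
#'
#' @param params a [model_parameters()].
#' @param init initial state.
#' @param weights a [control_weights()].
#' @param config an [oc_config()].
#' @return List of class `oc_result`: `trajectory`, `adjoints`, `controls`
#'   (data.frames on the grid), `J`, `iterations`, `converged`, `J_history`,
#'   `control_change`.
#' @export
forward_backward_sweep <- function(params, init,
                                   weights = control_weights(),
                                   config = oc_config()) {
  times <- seq(0, config$t_f, length.out = config$n_grid)
  n <- config$n_grid
  u <- matrix(0, n, 3, dimnames = list(NULL, c("u1", "u2", "u3")))
  u[, !config$mask] <- 0
  states <- NULL
  adjoints <- NULL
  J_history <- numeric(0)
  converged <- FALSE
  change <- NA_real_
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    u_ctrl <- cbind(times, u)
    states <- rk4_integrate(params, init, times, controls = u_ctrl)
    adjoints <- backward_adjoint_rk4(times, states, u, params, weights)
    u_new <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      u_new[i, ] <- optimal_control_update(states[i, ], adjoints[i, ],
                                           weights, config$mask)
    }
    u_next <- (1 - config$relax) * u + config$relax * u_new
    change <- max(vapply(1:3, function(j) {
      max(abs(u_next[, j] - u[, j])) / max(1, max(abs(u_next[, j])))
    }, numeric(1)))
    u <- u_next
    traj <- as.data.frame(states)
    traj$time <- times
    J_history <- c(J_history, objective_value(traj, u, weights))
    if (change < config$tol) { converged <- TRUE; break }
  }
  traj <- data.frame(time = times, states, check.names = FALSE)
  class(traj) <- c("depression_trajectory", "data.frame")
  adj <- data.frame(time = times, adjoints)
  names(adj) <- c("time", paste0("Lambda", 1:7))
  ctrl <- data.frame(time = times, u)
  structure(list(trajectory = traj, adjoints = adj, controls = ctrl,
                 J = J_history[length(J_history)],
                 iterations = iter, converged = converged,
                 J_history = J_history, control_change = change),
            class = "oc_result")
}

# Backward RK4 pass for the adjoints: integrates dLambda/dt = -dH/dx from
# Lambda(t_f) = 0 to t = 0, interpolating states and controls linearly at
# half-steps.
backward_adjoint_rk4 <- function(times, states, u, params, weights) {
  n <- length(times)
  lam <- matrix(0, n, 7)
  rhs <- function(x, l, uu) adjoint_rhs(x, l, uu, params, weights)
  for (i in seq(n, 2)) {
    h <- times[i] - times[i - 1]
    x1 <- states[i, ]; x0 <- states[i - 1, ]; xm <- (x1 + x0) / 2
    u1 <- u[i, ]; u0 <- u[i - 1, ]; um <- (u1 + u0) / 2
    l <- lam[i, ]
    k1 <- rhs(x1, l, u1)
    k2 <- rhs(xm, l - h / 2 * k1, um)
    k3 <- rhs(xm, l - h / 2 * k2, um)
    k4 <- rhs(x0, l - h * k3, u0)
    lam[i - 1, ] <- l - h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  lam
}

STRATEGY_MASKS <- list(A = c(TRUE, FALSE, FALSE),
                       B = c(FALSE, TRUE, FALSE),
                       C = c(FALSE, FALSE, TRUE),
                       D = c(TRUE, TRUE, FALSE),
                       E = c(FALSE, TRUE, TRUE),
                       F = c(TRUE, FALSE, TRUE),
                       G = c(TRUE, TRUE, TRUE))

#' Run the seven control strategies plus the uncontrolled baseline
#'
#' Strategies A-C use a single control (u1, u2, u3 respectively), D-F the
#' three pairs, and G all three; the baseline runs the plain uncontrolled
#' model on the same grid. Reports the objective J, the terminal
#' secondary-depressed count D(t_f), and the percent reduction of D(t_f)
#' against baseline for each strategy.
#'
#' @inheritParams forward_backward_sweep
#' @param strategies subset of `c("A","B","C","D","E","F","G")`.
#' @return List of class `strategy_comparison` with `table` (one row per
#'   run) and `results` (named list of `oc_result`s, plus `baseline`).
#' @export
run_strategies <- function(params, init, weights = control_weights(),
                           config = oc_config(),
                           strategies = names(STRATEGY_MASKS)) {
  times <- seq(0, config$t_f, length.out = config$n_grid)
  base_states <- rk4_integrate(params, init, times)
  base_traj <- data.frame(time = times, base_states, check.names = FALSE)
  class(base_traj) <- c("depression_trajectory", "data.frame")
  zero_u <- matrix(0, config$n_grid, 3)
  base_J <- objective_value(base_traj, zero_u, weights)
  base_D <- base_traj$D[config$n_grid]
  rows <- list(data.frame(strategy = "baseline", J = base_J, D_at_tf = base_D,
                          percent_reduction_vs_baseline = 0,
                          converged = TRUE, iterations = 0L))
  results <- list(baseline = list(trajectory = base_traj, J = base_J))
  for (s in strategies) {
    cfg <- config
    cfg$mask <- STRATEGY_MASKS[[s]]
    res <- forward_backward_sweep(params, init, weights, cfg)
    D_tf <- res$trajectory$D[config$n_grid]
    rows[[length(rows) + 1]] <-
      data.frame(strategy = s, J = res$J, D_at_tf = D_tf,
                 percent_reduction_vs_baseline = 100 * (base_D - D_tf) / base_D,
                 converged = res$converged, iterations = res$iterations)
    results[[s]] <- res
  }
  structure(list(table = do.call(rbind, rows), results = results),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("Optimal-control strategy comparison:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Export the strategy table / control profiles as CSV
#'
#' @param comparison a [run_strategies()] result.
#' @param result an `oc_result` whose control profiles to export.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_strategy_csv <- function(comparison, path) {
  df <- comparison$table
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_strategy_csv
#' @export
write_control_profile_csv <- function(result, path) {
  df <- result$controls
  df[] <- lapply(df, function(v) signif(v, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
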