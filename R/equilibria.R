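#' Closed-form equilibria E0, E1 and (best-effort) E2
#'
#' E0 is the susceptible-only steady state (Lambda/mu, 0, ..., 0); E1 is the
#' saboteur-present, depression-free state with S* = Lambda/beta1 and
#' B* = (beta1/mu - 1) Lambda/beta1, which exists only when beta1 > mu. The
#' saboteur-free endemic state E2 is evaluated verbatim from its published
#' constant chain (a1..a6); those constants do not dimension-check, so E2 is
#' reported best-effort with its residual recorded — never assumed to be an
#' equilibrium. Numerical root finding
#' ([solve_equilibria_numeric()]) is the source of truth for E2/E3.
#'
#' @param params a [model_parameters()] object.
#' @return List of equilibrium reports (see [equilibrium_report()]); E1 is
#'   omitted (with a `skipped` entry) when beta1 <= mu.
#' @export
closed_form_equilibria <- function(params) {
  out <- list()
  e0 <- state_vector(S = params$Lambda / params$mu)
  out$E0 <- equilibrium_report(e0, params, label = "E0")
  if (params$beta1 >= params$mu) {
    # at beta1 == mu the saboteur count B* vanishes and E1 coincides with E0
    s1 <- params$Lambda / params$beta1
    b1 <- (params$beta1 / params$mu - 1) * params$Lambda / params$beta1
    out$E1 <- equilibrium_report(state_vector(S = s1, B = b1), params,
                                 label = "E1")
  } else {
    notes <- c(notes = paste0("E1 requires beta1 > mu (beta1 = ", params$beta1,
                              ", mu = ", params$mu, ")"))
    attr(out, "notes") <- c(attr(out, "notes"), notes)
  }
  e2 <- tryCatch(e2_printed(params), error = function(e) NULL)
  if (!is.null(e2) && all(is.finite(e2)) && all(e2 >= 0)) {
    out$E2 <- equilibrium_report(e2, params, label = "E2",
                                 require_equilibrium = FALSE)
  } else {
    attr(out, "notes") <- c(attr(out, "notes"),
      "published E2 construction gave a non-finite or negative state; use solve_equilibria_numeric()")
  }
  out
}

# Verbatim transcription of the published saboteur-free equilibrium
# construction. Kept only as a recorded cross-check: the constants mix
# dimensions (a4 adds the dimensionless a1 to rate products), so the residual
# of the resulting state is reported rather than assumed zero.
e2_printed <- function(params) {
  with(params, {
    a1 <- psi1 / (gamma1 + mu)
    a2 <- psi2 / (mu + gamma2)
    a3 <- psi2 + mu + sigma
    a4 <- (lambda2 * (mu + omega) + a1) / (a3 * (mu + omega) - a2)
    a5 <- lambda2 + mu + psi1
    a6 <- a3 * a4 / lambda2 + a4 + a1 + a2 * a4 +
      (lambda2 - omega) * (gamma1 * a1 + a2 * a4 * gamma2) /
        (lambda2 * (mu + omega))
    Pst <- Lambda * (1 - a4) / (sigma * a4 - a5 * a4 + a6 * mu)
    Sst <- (Lambda * a4 - a5 * a4) / mu * Pst
    Dst <- a4 * Pst
    Mst <- a1 * Pst
    Cst <- a2 * Dst
    Rst <- (gamma1 * a1 * Pst + gamma2 * a2 * Dst) / (mu + omega)
    c(S = Sst, B = 0, P = Pst, D = Dst, M = Mst, C = Cst, R = Rst)
  })
}

#' Equilibrium report: residual, eigenvalues, stability class
#'
#' Evaluates the model right-hand side at a candidate state, the Jacobian
#' eigenvalues there, and a stability label from the eigenvalue real parts
#' (see [classify_eigenvalues()]).
#'
#' @param state candidate state (7 components, non-negative).
#' @param params a [model_parameters()] object.
#' @param label equilibrium label (`"E0"`, `"E1"`, `"E2"`, `"E3"` or
#'   `"numeric"`).
#' @param require_equilibrium if `TRUE` (default) an error is raised when the
#'   residual exceeds `1e-9 * max(1, N)`; set `FALSE` to report a
#'   non-equilibrium candidate (e.g. the verbatim printed E2).
#' @return List of class `equilibrium_report` with fields `label`, `state`,
#'   `residual_norm`, `eigenvalues`, `stability`, `is_equilibrium`.
#' @export
equilibrium_report <- function(state, params, label = "numeric",
                               require_equilibrium = TRUE) {
  x <- as_state(state)
  if (sum(x) == 0) {
    # the origin: frequency-dependent terms vanish with the population, the
    # only remaining flow is recruitment; the Jacobian limit is direction
    # dependent, so no stability claim is made there
    res <- abs(params$Lambda)
    if (require_equilibrium && res > 1e-9) {
      stop("the origin is not an equilibrium unless Lambda = 0")
    }
    return(structure(list(label = label, state = x, residual_norm = res,
                          eigenvalues = rep(NA_complex_, 7),
                          stability = "marginal",
                          is_equilibrium = res <= 1e-9),
                     class = "equilibrium_report"))
  }
  res <- max(abs(depression_rhs(x, params)))
  tol <- 1e-9 * max(1, sum(x))
  if (require_equilibrium && res > tol) {
    stop("state is not an equilibrium: residual ", format(res),
         " exceeds ", format(tol))
  }
  ev <- eigen(model_jacobian(x, params), only.values = TRUE)$values
  structure(list(label = label, state = x, residual_norm = res,
                 eigenvalues = ev,
                 stability = classify_eigenvalues(ev),
                 is_equilibrium = res <= tol),
            class = "equilibrium_report")
}

#' Stability class from Jacobian eigenvalues
#'
#' `stable` if every real part is below `-eps`, `unstable` if any exceeds
#' `+eps`, otherwise `marginal`, with `eps = 1e-8` times the spectral scale.
#' Marginal cases are never silently promoted to stable.
#'
#' @param eigenvalues complex eigenvalues of the Jacobian.
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @export
classify_eigenvalues <- function(eigenvalues) {
  re <- Re(eigenvalues)
  eps <- 1e-8 * max(abs(eigenvalues), 1)
  if (all(re < -eps)) "stable" else if (any(re > eps)) "unstable" else "marginal"
}

#' Stability of an equilibrium report
#'
#' Re-derives the stability label of a report at possibly different
#' parameters (the report's state must still be an equilibrium there).
#'
#' @param report an [equilibrium_report()].
#' @param params a [model_parameters()] object.
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @export
classify_stability <- function(report, params) {
  ev <- eigen(model_jacobian(report$state, params), only.values = TRUE)$values
  classify_eigenvalues(ev)
}

#' Coefficients of the endemic total-population quintic
#'
#' The endemic equilibrium's total population N solves a degree-5 polynomial
#' Q1 N^5 + ... + Q5 N + Q6 = 0 built from auxiliary constants (a1..a4,
#' b1..b3, A1..A3, C1..C5). The published W-coefficient expressions contain
#' transcription irregularities (unbalanced parentheses, a bare "A"); this
#' transcription resolves them minimally and is used for Descartes sign
#' analysis and cross-checks only — numerical root finding is the source of
#' truth for the endemic state itself.
#'
#' @param params a [model_parameters()] object.
#' @return List with `coefficients` (Q1..Q6, highest degree first) and the
#'   auxiliary constants, class `quintic_coefficients`.
#' @export
quintic_coefficients <- function(params) {
  k <- with(params, {
    a1 <- psi1 / (gamma1 + mu)
    a2 <- psi2 / (mu + gamma2)
    a3 <- psi2 + mu + sigma
    a4 <- lambda2 + mu + psi1
    b1 <- gamma1 * a1 / (mu + omega)
    b2 <- gamma2 * a2 / (mu + omega)
    b3 <- mu * beta2 / beta1
    A1 <- a4 * a3 * beta1 * (a3 - b2) - (lambda2 + b1) * mu * beta2
    A2 <- lambda1 * a3 * (a3 - b2)
    A3 <- mu * beta2 * lambda1 / beta1
    C1 <- Lambda * A2 * beta1 - mu * A1 * beta1
    C2 <- beta1 * A3 * Lambda + mu^2 * A2
    C3 <- mu^2 * A3
    C4 <- beta1 * A2
    C5 <- beta1 * A3
    list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, b1 = b1, b2 = b2, b3 = b3,
         A1 = A1, A2 = A2, A3 = A3,
         C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5)
  })
  p <- params
  Q1 <- (1 + k$a1 + k$b1) * k$b3 * p$beta1 * k$A3^2 * k$C3
  Q2 <- (2 + k$a2 + k$b2 + p$mu) * k$A3^2 * k$C5 * k$a4 -
    (1 + k$a1 + k$b1) * k$b3 * p$beta1 * (2 * k$A2 * k$A3 * k$C3 + k$A3^2 * k$C2)
  Q3 <- k$a4 * k$A3 * (p$mu * (k$A3 * k$C4 + k$A2 * k$C5) - (k$a3 + k$C5)) +
    (p$mu - 1) * (p$lambda1 * k$A1 + k$a4 * k$A2) * k$A3 * k$C5 +
    (1 + k$a1 + k$b1) * k$b3 * p$beta1 *
      (k$C1 * k$A3^2 + k$A2^2 * k$C3 + 2 * k$A2 * k$A3 * k$C2) -
    (1 + k$a2 + k$b2) *
      (k$C3 * k$A3 * (p$lambda1 * k$A1 + k$a4 * k$A2) +
         k$A2 * k$A3 * k$a4 + k$C2 * k$a4 * k$A3^2)
  Q4 <- (p$lambda1 * k$A1 - 1 + k$a4) *
    (k$A3 + k$C5 - p$mu * (k$A3 * k$C4 + k$A2 * k$C5) +
       3 * (1 + k$a2 + k$b2) * k$C3 * k$A2) +
    k$a4 * k$A3 * (k$A2 * k$C4 - p$mu * k$A2 * k$C4 + k$A1 * p$beta1 * k$C5 +
                     k$A2 * (1 + k$a2 + k$b2) + k$C1 * k$A3) -
    k$b3 * p$beta1 * (1 + k$a1 + k$b1) * (2 * k$A2 * k$A3 * k$C1 + k$C2 * k$A2^2)
  Q5 <- (p$lambda1 * k$A1 + k$a4 * k$A2) *
    (p$mu * k$A2 * k$C4 - k$A2 * k$C4 - k$A1 * p$beta1 * k$C5 -
       (1 + k$a2 + k$b2) * (k$C2 * k$A2 + k$C1 * k$A3)) -
    k$A1 * p$beta1 * k$a4 * k$A3 * k$C4 +
    (1 + k$a1 + k$b1) * k$b3 * p$beta1 * k$A2^2 * k$C1 -
    (1 + k$a2 + k$b2) * k$C1 * k$A2 * k$A3 * k$a4
  a5 <- p$lambda2 + p$mu + p$psi1
  Q6 <- k$A1 * p$beta1 * k$C4 * (p$lambda1 * k$A1 + a5 * k$A2) +
    (1 + k$a2 + k$b2) * k$A2 * k$C1 * (p$lambda1 * k$A1 + a5 * k$A2)
  structure(c(list(coefficients = c(Q1 = Q1, Q2 = Q2, Q3 = Q3,
                                    Q4 = Q4, Q5 = Q5, Q6 = Q6)), k),
            class = "quintic_coefficients")
}

#' Descartes' rule-of-signs bounds on real roots
#'
#' Given polynomial coefficients ordered from the highest degree down,
#' returns the possible numbers of positive real roots (sign changes of
#' p(N), stepping down by 2) and of negative real roots (sign changes of
#' p(-N)). Internal zero coefficients are skipped, leading zeros stripped.
#'
#' @param coefficients numeric vector, highest degree first.
#' @return List with `positive` and `negative`, each a decreasing integer
#'   vector of possible root counts, plus the two sign-change counts.
#' @export
descartes_bounds <- function(coefficients) {
  co <- as.numeric(coefficients)
  if (all(co == 0)) stop("all coefficients are zero: not a polynomial")
  co <- co[which(co != 0)[1]:length(co)]
  degrees <- rev(seq_along(co)) - 1
  changes <- function(v) {
    s <- sign(v[v != 0])
    sum(s[-1] != s[-length(s)])
  }
  vpos <- changes(co)
  vneg <- changes(co * (-1)^degrees)
  steps <- function(v) if (v == 0) 0L else seq.int(v, v %% 2, by = -2)
  list(positive = steps(vpos), negative = steps(vneg),
       sign_changes_pos = vpos, sign_changes_neg = vneg)
}

#' Numerical equilibria by damped multi-start Newton iteration
#'
#' Finds roots of the model right-hand side in the non-negative orthant.
#' Starts are deterministic: a seeded Latin-hypercube scatter in
#' [0, Lambda/mu]^7, the closed-form E0/E1 states, and the long-run state of
#' a forward simulation (which seeds the attracting endemic equilibrium when
#' R0 > 1). Newton steps use the analytic Jacobian with step halving;
#' converged roots are verified (residual recorded), clamped at zero,
#' deduplicated at 1e-6 relative tolerance and labelled by their zero
#' pattern (E0: only S; E1: no depression; E2: no saboteurs; E3: all
#' positive).
#'
#' @param params a [model_parameters()] object.
#' @param n_starts number of Latin-hypercube starts.
#' @param seed integer seed making the scatter reproducible.
#' @return List of [equilibrium_report()]s, each with a `start` attribute;
#'   empty (with a `diagnostics` attribute) if nothing converged.
#' @export
solve_equilibria_numeric <- function(params, n_starts = 32, seed = 1) {
  cap <- params$Lambda / params$mu
  starts <- list()
  lh <- withr::with_seed(seed, lhs::randomLHS(n_starts, 7))
  for (i in seq_len(n_starts)) starts[[i]] <- as.numeric(lh[i, ]) * cap
  starts <- c(starts, list(c(cap, 0, 0, 0, 0, 0, 0)))
  if (params$beta1 > params$mu) {
    s1 <- params$Lambda / params$beta1
    starts <- c(starts, list(c(s1, (params$beta1 / params$mu - 1) * s1,
                               0, 0, 0, 0, 0)))
  }
  long_run <- tryCatch({
    init <- rep(cap / 7, 7)
    traj <- simulate_depression(params, init, c(0, 10^seq(0, 3, by = 0.5)))
    as.numeric(traj[nrow(traj), COMPARTMENTS])
  }, error = function(e) NULL)
  if (!is.null(long_run)) starts <- c(starts, list(long_run))

  roots <- list()
  tried <- 0L
  for (x0 in starts) {
    tried <- tried + 1L
    root <- newton_root(x0, params, cap)
    if (is.null(root)) next
    dup <- any(vapply(roots, function(r) {
      max(abs(r - root)) <= 1e-6 * max(1, cap)
    }, logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- root
  }
  if (!length(roots)) {
    out <- list()
    attr(out, "diagnostics") <- paste("no Newton start converged out of", tried)
    return(out)
  }
  reports <- lapply(roots, function(r) {
    zero <- r <= 1e-6 * max(1, cap)
    label <- if (all(zero[2:7])) "E0"
      else if (!zero[2] && all(zero[3:7])) "E1"
      else if (zero[2]) "E2"
      else if (!any(zero)) "E3"
      else "numeric"
    equilibrium_report(r, params, label = label, require_equilibrium = FALSE)
  })
  # keep only verified equilibria
  reports[vapply(reports, function(r) r$is_equilibrium, logical(1))]
}

# Damped Newton iteration on the rhs, restricted to the non-negative orthant.
newton_root <- function(x0, params, cap) {
  x <- pmax(as.numeric(x0), 0)
  if (sum(x) <= 0) x[1] <- max(cap * 1e-3, 1e-8)
  tol <- 1e-12 * max(1, cap)
  for (it in 1:100) {
    f <- tryCatch(depression_rhs(x, params), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    if (max(abs(f)) < tol) break
    J <- model_jacobian(x, params)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # step halving with projection keeps N positive and damps overshoot
    lam <- 1
    repeat {
      xn <- pmax(x - lam * step, 0)
      fn <- if (sum(xn) > 0) {
        tryCatch(max(abs(depression_rhs(xn, params))), error = function(e) Inf)
      } else Inf
      if (fn < max(abs(f)) || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6 && fn >= max(abs(f))) return(NULL)
    x <- xn
  }
  f <- tryCatch(depression_rhs(x, params), error = function(e) NULL)
  if (is.null(f) || max(abs(f)) > 1e-9 * max(1, sum(x))) return(NULL)
  x
}

#' Export equilibrium reports as CSV
#'
#' One row per equilibrium: label, the seven states, residual norm, maximum
#' eigenvalue real part and the stability class.
#'
#' @param reports list of [equilibrium_report()]s.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_equilibria_csv <- function(reports, path) {
  reports <- Filter(function(r) inherits(r, "equilibrium_report"), reports)
  rows <- lapply(reports, function(r) {
    data.frame(label = r$label, t(signif(r$state, 12)),
               residual = signif(r$residual_norm, 12),
               max_re_eigenvalue = signif(max(Re(r$eigenvalues)), 12),
               stability = r$stability)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
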