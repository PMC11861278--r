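#' Closed-form basic reproduction number
#'
#' R0 for the depression model, derived by the next-generation-matrix method
#' with the infected set (P, D, M, C) linearised at the saboteur-present
#' depression-free equilibrium E1 (so the saboteur aggravation enters through
#' the equilibrium ratio B*/N* = (beta1 - mu)/beta1 — an unusual but
#' deliberate choice: saboteurs persist whenever beta1 > mu, and the relevant
#' invasion question is whether depression can spread in their presence):
#'
#' \deqn{R_0 = \frac{\beta_2(\beta_1\lambda_1 + \beta_1\lambda_2 -
#'   \lambda_1\mu)}{(\mu+\psi_2+\sigma)(\beta_1\lambda_1 + \beta_1\lambda_2 +
#'   \beta_1\mu + \beta_1\psi_1 - \lambda_1\mu)}}
#'
#' @param params a [model_parameters()] object with `beta1 > mu` (or
#'   `lambda1 = 0`, in which case the saboteur ratio drops out).
#' @return Scalar R0.
#' @export
r0_closed_form <- function(params) {
  num_inner <- params$beta1 * params$lambda1 + params$beta1 * params$lambda2 -
    params$lambda1 * params$mu
  den_inner <- num_inner + params$beta1 * params$mu + params$beta1 * params$psi1
  if (params$beta1 <= params$mu && (num_inner <= 0 || den_inner <= 0)) {
    stop("R0 closed form requires beta1 > mu (saboteur-present equilibrium): ",
         "beta1 = ", params$beta1, ", mu = ", params$mu)
  }
  if (den_inner <= 0) stop("R0 denominator non-positive; parameters outside validity region")
  params$beta2 * num_inner /
    ((params$mu + params$psi2 + params$sigma) * den_inner)
}

#' Next-generation matrices F, V and K = F V^-1
#'
#' Builds the 4x4 new-infection matrix F (single nonzero entry beta2 in the
#' P row, D column) and the transition matrix V of the infected subsystem
#' (P, D, M, C) linearised at E1, where the saboteur term contributes
#' `lambda1 (beta1 - mu)/beta1` to the P outflow and D inflow. The spectral
#' radius of K is the basic reproduction number; K has a single nonzero row,
#' so all but one of its eigenvalues are zero.
#'
#' @param params a [model_parameters()] object with `beta1 > mu`.
#' @return List with `F`, `V`, `K`, `spectral_radius`, `R0_closed_form` and
#'   `infected_ordering = c("P","D","M","C")`, class `ngm_result`.
#' @export
next_generation_matrices <- function(params) {
  if (params$beta1 <= params$mu) {
    stop("next-generation matrices are evaluated at E1 and require beta1 > mu")
  }
  sab <- params$lambda1 * (params$beta1 - params$mu) / params$beta1
  ord <- c("P", "D", "M", "C")
  Fm <- matrix(0, 4, 4, dimnames = list(ord, ord))
  Fm["P", "D"] <- params$beta2
  Vm <- matrix(0, 4, 4, dimnames = list(ord, ord))
  Vm["P", "P"] <- params$lambda2 + params$mu + params$psi1 + sab
  Vm["D", "P"] <- -params$lambda2 - sab
  Vm["D", "D"] <- params$mu + params$psi2 + params$sigma
  Vm["M", "P"] <- -params$psi1
  Vm["M", "M"] <- params$gamma1 + params$mu
  Vm["C", "D"] <- -params$psi2
  Vm["C", "C"] <- params$gamma2 + params$mu
  K <- Fm %*% solve(Vm)
  rho <- max(abs(eigen(K, only.values = TRUE)$values))
  structure(list(F = Fm, V = Vm, K = K,
                 spectral_radius = rho,
                 R0_closed_form = r0_closed_form(params),
                 infected_ordering = ord),
            class = "ngm_result")
}

R0_PARAMETERS <- c("beta1", "beta2", "lambda1", "lambda2",
                   "psi1", "psi2", "sigma", "mu")

#' Normalized forward sensitivity index (elasticity) of R0
#'
#' The elasticity (dR0/dp) * (p/R0): the proportional change in R0 per
#' proportional change in a parameter. Computed by central finite differences
#' with relative step 1e-6 on the closed form; only the eight parameters that
#' enter R0 are supported (`gamma1`, `gamma2`, `omega` and `Lambda` do not).
#'
#' @param params a [model_parameters()] object with `R0 > 0`.
#' @param parameter one of `"beta1","beta2","lambda1","lambda2","psi1",
#'   "psi2","sigma","mu"`.
#' @param rel_step relative finite-difference step.
#' @return List `(parameter, elasticity)` of class `sensitivity_index`.
#' @export
r0_elasticity <- function(params, parameter, rel_step = 1e-6) {
  if (!parameter %in% R0_PARAMETERS) {
    stop("unsupported parameter '", parameter,
         "': R0 depends only on ", paste(R0_PARAMETERS, collapse = ", "))
  }
  p0 <- params[[parameter]]
  if (p0 <= 0) stop("elasticity undefined at ", parameter, " = 0")
  r0 <- r0_closed_form(params)
  if (r0 <= 0) stop("elasticity undefined where R0 = 0")
  h <- rel_step * p0
  set_one <- function(v) {
    do.call(update_parameters, c(list(params), stats::setNames(list(v), parameter)))
  }
  up <- r0_closed_form(set_one(p0 + h))
  dn <- r0_closed_form(set_one(p0 - h))
  structure(list(parameter = parameter,
                 elasticity = (up - dn) / (2 * h) * p0 / r0),
            class = "sensitivity_index")
}

#' Elasticity profile over all eight R0 parameters
#'
#' @inheritParams r0_elasticity
#' @return Data frame with columns `parameter`, `elasticity`, one row per
#'   parameter in the order beta1, beta2, lambda1, lambda2, psi1, psi2,
#'   sigma, mu.
#' @export
elasticity_profile <- function(params) {
  data.frame(
    parameter = R0_PARAMETERS,
    elasticity = vapply(R0_PARAMETERS,
                        function(nm) r0_elasticity(params, nm)$elasticity,
                        numeric(1)),
    row.names = NULL)
}

#' R0 over a two-parameter grid (contour analysis)
#'
#' Evaluates the closed-form R0 over the outer grid of two parameter ranges.
#' Grid cells falling outside the validity region (beta1 <= mu with a
#' non-positive denominator) are flagged `NA`, never silently dropped.
#'
#' @param params baseline [model_parameters()].
#' @param param_a,param_b names of the two varied parameters.
#' @param range_a,range_b numeric vectors of values, or length-2 bounds used
#'   with `resolution`.
#' @param resolution grid points per axis when bounds are given.
#' @return Matrix of R0 values, rows indexed by `range_a` values (dimnames
#'   carry the axis values).
#' @export
r0_grid <- function(params, param_a, range_a, param_b, range_b,
                    resolution = 25) {
  expand_axis <- function(r) {
    if (length(r) == 2) seq(r[1], r[2], length.out = resolution) else r
  }
  a <- expand_axis(range_a); b <- expand_axis(range_b)
  out <- matrix(NA_real_, length(a), length(b),
                dimnames = list(signif(a, 8), signif(b, 8)))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      repl <- stats::setNames(list(a[i], b[j]), c(param_a, param_b))
      p <- tryCatch(do.call(update_parameters, c(list(params), repl)),
                    error = function(e) NULL)
      if (is.null(p)) next
      out[i, j] <- tryCatch(r0_closed_form(p), error = function(e) NA_real_)
    }
  }
  out
}

#' Write an R0 grid or elasticity profile as CSV
#'
#' @param grid matrix from [r0_grid()].
#' @param profile data.frame from [elasticity_profile()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_r0_grid_csv <- function(grid, path) {
  df <- data.frame(value_a = rownames(grid), signif(grid, 12),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_r0_grid_csv
#' @export
write_elasticity_csv <- function(profile, path) {
  profile$elasticity <- signif(profile$elasticity, 12)
  utils::write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
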