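#' Model parameters for the saboteur-depression model
#'
#' Constructs and validates the twelve rate constants of the compartmental
#' model. All rates are per year; `Lambda` is a recruitment flow
#' (individuals per year on whatever population scale the analysis uses),
#' the remaining parameters are first-order rates.
#'
#' @param Lambda recruitment flow into the susceptible class (individuals/yr).
#' @param beta1 saboteur contact rate: S -> B by contact with B (1/yr).
#' @param beta2 depression transmission rate: S -> P by contact with D (1/yr).
#' @param lambda1 saboteur aggravation rate: P -> D by contact with B (1/yr).
#' @param lambda2 spontaneous progression rate P -> D (1/yr).
#' @param psi1 uptake of non-pharmacological treatment, P -> M (1/yr).
#' @param psi2 uptake of pharmacological treatment, D -> C (1/yr).
#' @param gamma1 recovery rate from non-pharmacological treatment, M -> R (1/yr).
#' @param gamma2 recovery rate from pharmacological treatment, C -> R (1/yr).
#' @param sigma depression-attributable death rate from D (1/yr).
#' @param omega relapse rate R -> D (1/yr).
#' @param mu natural (all-cause) death rate in every compartment (1/yr).
#'
#' @return An object of class `model_parameters`: a named list of the twelve
#'   rates with a `saboteur_viable` attribute recording whether `beta1 > mu`
#'   (required for the saboteur-present equilibrium E1 and for the
#'   next-generation matrix evaluated there).
#' @seealso [spain_parameters()] for the published baseline values.
#' @export
model_parameters <- function(Lambda, beta1, beta2, lambda1, lambda2,
                             psi1, psi2, gamma1, gamma2, sigma, omega, mu) {
  p <- list(Lambda = Lambda, beta1 = beta1, beta2 = beta2,
            lambda1 = lambda1, lambda2 = lambda2,
            psi1 = psi1, psi2 = psi2, gamma1 = gamma1, gamma2 = gamma2,
            sigma = sigma, omega = omega, mu = mu)
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    stop("all model parameters must be finite numbers")
  }
  if (any(vals < 0)) {
    stop("model parameters must be non-negative; offending: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  }
  if (mu <= 0) stop("natural death rate 'mu' must be strictly positive")
  structure(p, class = "model_parameters",
            saboteur_viable = beta1 > mu)
}

#' Published baseline parameter set (Spain calibration)
#'
#' The literature/assumed rates together with the fitted contact and recovery
#' rates (beta1 = 0.5665, beta2 = 0.1567, gamma2 = 0.9219). The recruitment
#' flow is the per-capita birth rate 7.816e-4/yr times `ref_pop`, so with the
#' default `ref_pop = 1` the model works in "per capita" units and the
#' carrying scale is Lambda/mu = 0.0625; set `ref_pop` to an absolute
#' population (e.g. 4.7e7) to work in persons.
#'
#' @param ref_pop reference population multiplying the per-capita birth rate.
#' @param birth_rate per-capita birth rate (1/yr).
#' @return A [model_parameters()] object.
#' @export
spain_parameters <- function(ref_pop = 1, birth_rate = 7.816e-4) {
  model_parameters(
    Lambda = birth_rate * ref_pop,
    beta1 = 0.5665, beta2 = 0.1567,
    lambda1 = 0.2145, lambda2 = 0.7,
    psi1 = 0.0045, psi2 = 0.02,
    gamma1 = 0.6, gamma2 = 0.9219,
    sigma = 0.01, omega = 0.005, mu = 0.0125)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Saboteur-depression model parameters (per year):\n")
  print(unlist(x))
  cat(if (attr(x, "saboteur_viable")) "beta1 > mu: saboteur equilibrium E1 exists\n"
      else "beta1 <= mu: saboteurs die out, E1 coincides with/degenerates to E0\n")
  invisible(x)
}

#' Replace a subset of parameters
#'
#' @param params a [model_parameters()] object.
#' @param ... named scalar replacements, e.g. `beta2 = 0.2`.
#' @return A revalidated `model_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- unclass(params)
  p[names(repl)] <- repl
  do.call(model_parameters, p)
}

PARAM_NAMES <- c("Lambda", "beta1", "beta2", "lambda1", "lambda2",
                 "psi1", "psi2", "gamma1", "gamma2", "sigma", "omega", "mu")

COMPARTMENTS <- c("S", "B", "P", "D", "M", "C", "R")

#' Compartment state vector
#'
#' @param S,B,P,D,M,C,R compartment occupancies (individuals, same scale as
#'   `Lambda`): susceptible, saboteurs, primary depressed, secondary
#'   depressed, non-pharmacological treatment, pharmacological treatment,
#'   recovered.
#' @return Named numeric vector of length 7 with class `state_vector`.
#' @export
state_vector <- function(S = 0, B = 0, P = 0, D = 0, M = 0, C = 0, R = 0) {
  x <- c(S = S, B = B, P = P, D = D, M = M, C = C, R = R)
  if (any(!is.finite(x))) stop("state components must be finite")
  if (any(x < 0)) stop("state components must be non-negative; offending: ",
                       paste(names(x)[x < 0], collapse = ", "))
  structure(x, class = c("state_vector", "numeric"))
}

#' Total population of a state
#'
#' The total N is always the componentwise sum; it is never carried as a
#' separate state, which makes the identity N = S+B+P+D+M+C+R exact by
#' construction.
#'
#' @param state a numeric state vector (7 components).
#' @return Scalar total population.
#' @export
total_population <- function(state) sum(state[seq_len(7)])

as_state <- function(x) {
  if (length(x) != 7) stop("a state has exactly 7 components (S,B,P,D,M,C,R)")
  x <- as.numeric(x)
  names(x) <- COMPARTMENTS
  x
}

#' Read a model configuration file
#'
#' Parses a YAML configuration with a mandatory `parameters` block holding
#' exactly the twelve model rates (unknown keys are rejected), and optional
#' `reference_population`, `initial_fractions`, `control_weights`,
#' `control_bounds` and `horizon` blocks used by the analysis drivers.
#'
#' @param path path to a YAML file.
#' @return A list with elements `parameters` (a [model_parameters()] object)
#'   and any further blocks present in the file.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$parameters)) stop("config must contain a 'parameters' block")
  pars <- cfg$parameters
  unknown <- setdiff(names(pars), PARAM_NAMES)
  if (length(unknown)) {
    stop("unknown parameter key(s) in config: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(PARAM_NAMES, names(pars))
  if (length(missing)) {
    stop("config is missing parameter(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(cfg$reference_population)) {
    pars$Lambda <- pars$Lambda * cfg$reference_population
  }
  cfg$parameters <- do.call(model_parameters, pars)
  cfg
}
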