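#' Configuration for the synthetic prevalence-series generator
#'
#' The generator emulates the statistical structure the calibration assumes:
#' the model run at known "true" parameters, observed once a year through an
#' observable map, with multiplicative observation noise. Defaults are a
#' loosely Spain-shaped scenario — 12 yearly points starting in 2011, the
#' published baseline rates scaled to a 47-million reference population, and
#' a 2% coefficient of variation — but the series is synthetic, not the
#' Statista data. The default initial split (1% saboteurs, 2.5% primary and
#' 2.5% secondary depressed, nobody yet in treatment or recovered) matches
#' the calibration's initial-state rule, so the generator/fitter round trip
#' is coherent: the generating truth is the maximum-likelihood point of its
#' own noise-free output.
#'
#' @param params true [model_parameters()] used to simulate.
#' @param n0 initial total population (persons).
#' @param fractions initial compartment fractions (S,B,P,D,M,C,R), summing
#'   to 1.
#' @param start_year first calendar year.
#' @param n_years number of yearly observations (>= 2).
#' @param cv observation-noise coefficient of variation (>= 0).
#' @param noise `"gaussian"` (sd = cv * signal, truncated at zero; truncation
#'   biases the mean upward only at high cv) or `"poisson"` (cv ignored).
#' @param observable `"PD"` (reported cases = P + D, the total currently
#'   depressed), `"D"` (secondary depressed only), or `"PDMC"` (everyone
#'   currently ill or in treatment, P + D + M + C — the map that makes the
#'   pharmacological recovery rate `gamma2` statistically identifiable,
#'   since it drains C directly).
#' @param seed integer; all generator randomness flows through it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(params = spain_parameters(ref_pop = 4.7e7),
                             n0 = 4.7e7,
                             fractions = c(S = 0.94, B = 0.01, P = 0.025,
                                           D = 0.025, M = 0, C = 0, R = 0),
                             start_year = 2011, n_years = 12,
                             cv = 0.02, noise = c("gaussian", "poisson"),
                             observable = c("PD", "D", "PDMC"), seed = 1) {
  noise <- match.arg(noise)
  observable <- match.arg(observable)
  if (n_years < 2) stop("need at least 2 yearly observations")
  if (cv < 0) stop("noise level cv must be non-negative")
  if (n0 < 0) stop("initial population must be non-negative")
  structure(list(params = params, n0 = n0, fractions = fractions,
                 start_year = start_year, n_years = n_years, cv = cv,
                 noise = noise, observable = observable, seed = seed),
            class = "generator_config")
}

#' Deterministic initial state from compartment fractions
#'
#' Splits a target total population into the seven compartments by the
#' configured fractions; the components sum to `n0` exactly (the last
#' compartment absorbs rounding).
#'
#' @param config a [generator_config()].
#' @return A [state_vector()].
#' @export
generate_initial_state <- function(config) {
  fr <- as.numeric(config$fractions)
  if (length(fr) != 7) stop("fractions must have 7 components")
  if (any(fr < 0)) stop("fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-8) {
    stop("fractions must sum to 1 (got ", format(sum(fr)), ")")
  }
  x <- fr * config$n0
  x[7] <- config$n0 - sum(x[1:6])
  do.call(state_vector, as.list(stats::setNames(x, COMPARTMENTS)))
}

observable_map <- function(traj, observable) {
  switch(observable,
         PD = traj$P + traj$D,
         D = traj$D,
         PDMC = traj$P + traj$D + traj$M + traj$C,
         stop("unknown observable map: ", observable))
}

#' Generate a synthetic yearly prevalence series
#'
#' Simulates the model at the true parameters from the configured initial
#' state, reads the observable at yearly grid points, and adds seeded
#' observation noise: Gaussian with sd = cv * signal truncated at zero, or
#' Poisson with the signal as mean.
#'
#' @param config a [generator_config()].
#' @return A `prevalence_series`: data.frame with columns `year`, `cases`,
#'   carrying the noiseless signal as attribute `signal`.
#' @export
generate_prevalence_series <- function(config) {
  init <- generate_initial_state(config)
  times <- seq(0, config$n_years - 1)
  traj <- simulate_depression(config$params, init, times)
  signal <- observable_map(traj, config$observable)
  cases <- withr::with_seed(config$seed, switch(
    config$noise,
    gaussian = pmax(signal + stats::rnorm(length(signal),
                                          sd = config$cv * signal), 0),
    poisson = stats::rpois(length(signal), lambda = signal)))
  structure(data.frame(year = config$start_year + times, cases = cases),
            signal = signal,
            class = c("prevalence_series", "data.frame"))
}

#' Read / write a prevalence series CSV
#'
#' Dialect: header `year,cases`, one row per consecutive year, '.' decimal.
#' Malformed rows are rejected with the offending line number; years must be
#' strictly increasing with no duplicates.
#'
#' @param path CSV file path.
#' @param series a `prevalence_series` or data.frame with `year`, `cases`.
#' @return `read_prevalence_csv` returns a `prevalence_series`;
#'   `write_prevalence_csv` returns `path` invisibly.
#' @export
read_prevalence_csv <- function(path) {
  if (!file.exists(path)) stop("prevalence file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("year", "cases") %in% names(df))) {
    stop("prevalence CSV must have header 'year,cases'")
  }
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$year[i]) || !is.finite(df$cases[i]) || df$cases[i] < 0) {
      stop("malformed prevalence row at line ", i + 1L,
           " (year = ", df$year[i], ", cases = ", df$cases[i], ")")
    }
  }
  if (nrow(df) > 1 && any(diff(df$year) <= 0)) {
    bad <- which(diff(df$year) <= 0)[1] + 1L
    stop("years must be strictly increasing; violation at line ", bad + 1L)
  }
  structure(df[c("year", "cases")],
            class = c("prevalence_series", "data.frame"))
}

#' @rdname read_prevalence_csv
#' @export
write_prevalence_csv <- function(series, path) {
  df <- as.data.frame(series)[c("year", "cases")]
  df$cases <- signif(df$cases, 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
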