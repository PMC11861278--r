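# Shared fixtures: the published baseline rates and a seeded sampler of
# random valid parameter sets (all rates positive, beta1 > mu so the
# saboteur-present equilibrium and the next-generation machinery exist).

baseline_params <- function(ref_pop = 1) spain_parameters(ref_pop = ref_pop)

random_valid_params <- function(n = 1, seed = 42) {
  draws <- withr::with_seed(seed, lapply(seq_len(n), function(i) {
    mu <- runif(1, 0.005, 0.05)
    model_parameters(
      Lambda = runif(1, 1e-4, 1),
      beta1 = runif(1, mu * 1.5, 1),
      beta2 = runif(1, 0.01, 1),
      lambda1 = runif(1, 0.01, 1),
      lambda2 = runif(1, 0.01, 1),
      psi1 = runif(1, 0.001, 0.5),
      psi2 = runif(1, 0.001, 0.5),
      gamma1 = runif(1, 0.01, 1),
      gamma2 = runif(1, 0.01, 1),
      sigma = runif(1, 0.001, 0.1),
      omega = runif(1, 0.001, 0.1),
      mu = mu)
  }))
  if (n == 1) draws[[1]] else draws
}

random_positive_state <- function(scale = 1, seed = 7) {
  x <- withr::with_seed(seed, runif(7, 0.01, 1) * scale)
  names(x) <- c("S", "B", "P", "D", "M", "C", "R")
  x
}

# Desk-scale optimal-control scenario shared across control tests: the
# published rates on a 10,000-person reference population.
oc_scenario <- function() {
  params <- spain_parameters(ref_pop = 1e4)
  init <- generate_initial_state(generator_config(params = params, n0 = 1e4))
  list(params = params, init = init)
}
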