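#!/usr/bin/env Rscript
# Scenario runs of the uncontrolled model: 20-year trajectories under sweeps
# of the transmission, recovery and treatment rates, and the with/without
# saboteur comparison. Writes tidy horizon summaries under results/.

library(depressdyn)

dir.create("results", showWarnings = FALSE)
gcfg <- generator_config()
params <- gcfg$params
init <- generate_initial_state(gcfg)
horizon <- seq(0, 20, by = 0.25)

sweep_horizon <- function(name, factors = c(0.5, 1, 1.5)) {
  do.call(rbind, lapply(factors, function(f) {
    p <- do.call(update_parameters,
                 c(list(params), stats::setNames(list(f * params[[name]]), name)))
    tr <- simulate_depression(p, init, horizon)
    data.frame(parameter = name, value = f * params[[name]],
               P_plus_D_at_tf = tail(tr$P + tr$D, 1),
               recovered_at_tf = tail(tr$R, 1))
  }))
}

sweeps <- do.call(rbind, lapply(c("beta2", "gamma1", "gamma2", "psi1", "psi2"),
                                sweep_horizon))
utils::write.csv(sweeps, "results/scenario_sweeps.csv", row.names = FALSE)
cat("Scenario sweeps (P+D and R at 20 years):\n")
print(sweeps, row.names = FALSE)
cat("\nNote the direction of the gamma rows: faster recovery feeds the\n",
    "relapse loop (R -> D at rate omega), so P+D at the horizon rises\n",
    "slightly with gamma1/gamma2 even as the recovered pool grows.\n", sep = "")

# with / without saboteur interaction
no_sab <- update_parameters(params, lambda1 = 0, beta1 = 0)
for (tag in c("with", "without")) {
  p <- if (tag == "with") params else no_sab
  tr <- simulate_depression(p, init, horizon)
  write_trajectory_csv(tr, sprintf("results/trajectory_%s_saboteurs.csv", tag))
  cat(sprintf("%s saboteurs: P+D(20y) = %.0f\n", tag, tail(tr$P + tr$D, 1)))
}
cat("\nCounter-intuitively, removing saboteurs raises long-run depression\n",
    "here: the saboteur class competes for susceptibles, and at these rates\n",
    "the saboteur-present attractor is depression-free (see the methods\n",
    "vignette on stability of E1).\n", sep = "")
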