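#!/usr/bin/env Rscript
# Pontryagin optimal control of the depression model: forward-backward sweep
# under the published weights, the A-G strategy comparison, and the control
# profiles of the comprehensive strategy.

library(depressdyn)

dir.create("results", showWarnings = FALSE)
params <- spain_parameters(ref_pop = 1e4)
init <- generate_initial_state(generator_config(params = params, n0 = 1e4))
w <- control_weights()   # W1..W4 = 1, W5 = 15, W6 = 40, W7 = 55, bounds [0,1]

res <- forward_backward_sweep(params, init, w,
                              oc_config(t_f = 15, n_grid = 601, tol = 1e-6,
                                        max_iter = 400))
cat(sprintf("sweep converged in %d iterations; J = %.2f\n",
            res$iterations, res$J))
write_control_profile_csv(res, "results/control_profiles_G.csv")
write_trajectory_csv(res$trajectory, "results/trajectory_G.csv")

comp <- run_strategies(params, init, w,
                       oc_config(t_f = 15, n_grid = 301, tol = 1e-5,
                                 max_iter = 300))
print(comp)
write_strategy_csv(comp, "results/strategy_comparison.csv")
cat("\nThe comprehensive strategy G gives the largest reduction in\n",
    "secondary depression at the horizon; u2 (pharmacological uptake)\n",
    "stays at its upper bound longest, u3 adds little on its own because\n",
    "faster C -> R recovery feeds the relapse loop.\n", sep = "")

# discrepancy log between the exact adjoint gradient and the printed system
x <- as.numeric(res$trajectory[300, c("S", "B", "P", "D", "M", "C", "R")])
lam <- as.numeric(res$adjoints[300, -1])
u <- as.numeric(res$controls[300, -1])
d <- adjoint_rhs(x, lam, u, params, w) -
  adjoint_rhs_printed(x, lam, u, params, w)
cat(sprintf("\nmax |exact - printed| adjoint derivative at mid-run: %.3e\n",
            max(abs(d))))
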