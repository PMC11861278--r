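#!/usr/bin/env Rscript
# Maximum-likelihood calibration demonstrated end to end on a synthetic
# Spain-shaped prevalence series: generate at known rates, write/read the
# CSV, fit (beta1, beta2, gamma2), attach Wald intervals, and run a small
# replicate study of recovery error.

library(depressdyn)

dir.create("results", showWarnings = FALSE)
truth <- c(beta1 = 0.5665, beta2 = 0.1567, gamma2 = 0.9219)

gcfg <- generator_config(cv = 0.02, seed = 7, observable = "PDMC")
series <- generate_prevalence_series(gcfg)
write_prevalence_csv(series, "results/synthetic_prevalence.csv")
series <- read_prevalence_csv("results/synthetic_prevalence.csv")

cfg <- fit_config(n_starts = 4, seed = 7, observable = "PDMC")
fit <- wald_confidence_intervals(fit_mle(series, cfg), series, cfg)
print(fit)
write_fit_csv(fit, "results/fit_estimates.csv")
cat(sprintf("R0 at the estimate: %.4f\n", fit$r0))

cat("\nReplicate recovery study (10 replicates, CV = 2%):\n")
errs <- sapply(1:10, function(r) {
  s <- generate_prevalence_series(generator_config(cv = 0.02, seed = 700 + r,
                                                   observable = "PDMC"))
  f <- fit_mle(s, fit_config(n_starts = 3, seed = r, maxit = 250,
                             observable = "PDMC"))
  abs(f$estimates - truth) / truth
})
med <- apply(errs, 1, median)
print(round(100 * med, 1))
cat("Medians are percent relative error. beta1/beta2 recover to a few\n",
    "percent; gamma2 is weakly identified at this noise level because its\n",
    "influence reaches the case series only through the small treated\n",
    "compartment C (see the methods vignette).\n", sep = "")
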