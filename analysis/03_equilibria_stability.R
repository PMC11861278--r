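#!/usr/bin/env Rscript
# Equilibria of the model at the published rates: closed forms, multi-start
# numeric roots with stability classification, and the Descartes sign
# analysis of the endemic total-population quintic.

library(depressdyn)

dir.create("results", showWarnings = FALSE)
params <- spain_parameters()

eq <- closed_form_equilibria(params)
cat("Closed-form equilibria:\n")
for (nm in intersect(c("E0", "E1", "E2"), names(eq))) {
  r <- eq[[nm]]
  cat(sprintf("  %s: residual %.2e, stability %s\n",
              nm, r$residual_norm, r$stability))
}
notes <- attr(eq, "notes")
if (!is.null(notes)) cat("  note:", paste(notes, collapse = "; "), "\n")

roots <- solve_equilibria_numeric(params, n_starts = 32, seed = 1)
write_equilibria_csv(roots, "results/equilibria.csv")
cat(sprintf("\nNumeric roots found: %d\n", length(roots)))
for (r in roots) {
  cat(sprintf("  %s: D* = %.3e, residual %.2e, %s\n",
              r$label, r$state[["D"]], r$residual_norm, r$stability))
}

q <- quintic_coefficients(params)
b <- descartes_bounds(q$coefficients)
cat("\nQuintic coefficient signs:",
    paste(ifelse(q$coefficients >= 0, "+", "-"), collapse = " "), "\n")
cat("Descartes bounds: positive roots in {",
    paste(b$positive, collapse = ", "), "}, negative in {",
    paste(b$negative, collapse = ", "), "}\n")
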