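---
title: "Methods: saboteur-depression dynamics, calibration and optimal control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saboteur-depression dynamics, calibration and optimal control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depressdyn)
```

## The model

`depressdyn` implements a seven-compartment ordinary-differential-equation
model of depression spread in a well-mixed population. Susceptibles $S$ can
be recruited into a *saboteur* class $B$ — detractors who actively undermine
others' mental health — by contact at rate $\beta_1 B S/N$, or into primary
depression $P$ by contact with the severely (secondary) depressed $D$ at
rate $\beta_2 D S/N$. Primary depression worsens to secondary depression
spontaneously ($\lambda_2 P$) or through saboteur contact
($\lambda_1 B P/N$). Treatment is two-track: non-pharmacological uptake
$\psi_1 P \to M$ recovering at $\gamma_1$, and pharmacological uptake
$\psi_2 D \to C$ recovering at $\gamma_2$. Recovered individuals $R$ relapse
into $D$ at rate $\omega$. Everyone dies at the natural rate $\mu$ and the
secondary depressed additionally at $\sigma$; recruitment is a constant flow
$\Lambda$. All contact terms are frequency dependent (divided by
$N = S+B+P+D+M+C+R$), and $N$ is always recomputed as the compartment sum,
so the aggregate identity
$\dot N = \Lambda - \mu N - \sigma D$ holds exactly by construction
(internal transfers, including the controls, cancel in the sum).

One transcription choice deserves note: in the controlled system the
saboteur-aggravation term is sometimes written with $\lambda_2$; the flow
diagram, the uncontrolled system and dimensional consistency all demand
$\lambda_1 B P / N$, which is what `depression_rhs_controlled()` implements.

The time unit is years throughout ($\mu = 1/80$ per year), and the
population scale is configurable: `spain_parameters(ref_pop)` multiplies the
per-capita birth rate $7.816\times10^{-4}$/yr by a reference population, so
the same rates serve per-capita analyses (`ref_pop = 1`) and absolute-count
analyses (`ref_pop = 4.7e7`). Every quantity that matters scientifically
($R_0$, elasticities, stability, fitted rates) is invariant to this scale.

## Feasible region, integration, numerical choices

On the boundary faces of the non-negative orthant every flow points inward,
and $\dot N \le \Lambda - \mu N$, so
$\Omega_1 = \{0 \le S,\dots,R \le \Lambda/\mu\}$ is positively invariant.
`simulate_depression()` integrates with `deSolve::lsoda` at relative
tolerance $10^{-8}$ and absolute tolerance $10^{-10}\max(1, N_0)$;
undershoots below $-10^{-8}\max(1, N_0)$ raise an error, smaller ones are
clamped to zero in the returned table only. A fixed-step classical
Runge–Kutta integrator (`rk4_integrate()`) doubles as the independent
reference (trajectories agree to $10^{-6}$ relative against a $10\times$
finer RK4 grid) and as the workhorse of the control sweep.

## Reproduction number and sensitivity

The next-generation construction uses infected set $(P, D, M, C)$
linearised at the *saboteur-present* depression-free equilibrium
$E_1 = (\Lambda/\beta_1,\ (\beta_1/\mu - 1)\Lambda/\beta_1, 0, \dots)$,
which exists when $\beta_1 > \mu$: the saboteur ratio
$B^*/N^* = (\beta_1-\mu)/\beta_1$ enters the $P$-outflow and $D$-inflow of
the transition matrix $V$. This is unusual — most analyses linearise at the
fully disease-free state — but deliberate: saboteurs persist whenever
$\beta_1 > \mu$, so the relevant invasion question is whether depression
spreads in their presence. The closed form is

$$R_0 = \frac{\beta_2(\beta_1\lambda_1 + \beta_1\lambda_2 - \lambda_1\mu)}
{(\mu+\psi_2+\sigma)(\beta_1\lambda_1 + \beta_1\lambda_2 + \beta_1\mu +
\beta_1\psi_1 - \lambda_1\mu)},$$

which equals the spectral radius of $F V^{-1}$ to $10^{-8}$ over random
valid parameter draws. At the baseline rates it evaluates to
`r round(r0_closed_form(spain_parameters()), 4)`.

A caveat the package surfaces honestly: the new-infection matrix $F$ carries
the entry $\beta_2$, i.e. the transmission gradient evaluated with
$S/N = 1$ — the $E_0$ ratio — while $V$ uses $E_1$'s saboteur ratio. At
$E_1$ itself $S^*/N^* = \mu/\beta_1 \approx 0.022$, so this $R_0$ is *not*
the invasion threshold of $E_1$: at the baseline rates $R_0 = 3.62$ yet the
full Jacobian at $E_1$ has all eigenvalues in the left half-plane, and
long-run trajectories from interior states settle on $E_1$ (depression dies
out while saboteurs persist). The eigenvalue classifier, not the closed
form, is the package's arbiter of stability. Within the saboteur-free
invariant subspace ($B = 0$) the depression subsystem does change stability
as $R_0$ crosses one, which is the threshold property the tests exercise.

Sensitivity is reported as normalized forward indices (elasticities)
$(\partial R_0/\partial p)(p/R_0)$, computed by central differences with
relative step $10^{-6}$; the built-in self-tests are the exact results
$\Upsilon_{\beta_2} = 1$ (proportionality) and
$\Upsilon_\sigma = -\sigma/(\mu+\psi_2+\sigma)$. Only the eight parameters
in the closed form are accepted; $\gamma_1, \gamma_2, \omega, \Lambda$ do
not enter. Two-parameter grids (`r0_grid()`) mark cells outside the
validity region ($\beta_1 \le \mu$) as `NA` rather than evaluating a
different formula there.

## Equilibria and stability

Four families of steady states exist: extinction of both processes ($E_0$),
saboteurs only ($E_1$), depression without saboteurs ($E_2$) and full
coexistence ($E_3$). $E_0$ and $E_1$ have simple closed forms with machine-
precision residuals. The published closed-form construction for $E_2$ and
the quintic in $N$ whose positive roots index $E_3$ contain transcription
irregularities (constants that mix dimensions, unbalanced parentheses); the
package transcribes them verbatim — minimally repaired and documented where
unparseable — but treats them strictly as recorded cross-checks: at the
baseline rates the printed $E_2$ construction yields negative compartments
and is reported as skipped. The deliverable is `solve_equilibria_numeric()`:
damped multi-start Newton iteration on the exact right-hand side with the
analytic Jacobian, started from a seeded Latin-hypercube scatter in
$[0, \Lambda/\mu]^7$, the closed forms, and the long-run attractor of a
forward simulation; roots are verified (residual $\le 10^{-9}\max(1,N)$),
deduplicated at $10^{-6}$ relative, and labelled by their zero pattern. At
the baseline rates this finds $E_0$ (unstable, eigenvalue
$\beta_1 - \mu > 0$), the stable $E_1$, and an unstable saboteur-free
endemic $E_2$ with $D^* > 0$.

Stability is classified from the Jacobian spectrum with threshold
$\varepsilon = 10^{-8}$ times the spectral scale: `stable` below
$-\varepsilon$, `unstable` above $+\varepsilon$, otherwise `marginal` —
marginal cases are never promoted. The classifier is validated against a
simulation oracle: a 1% perturbation of a classified-stable equilibrium
contracts by at least $10\times$ over a long horizon.

Descartes' rule of signs (`descartes_bounds()`) bounds the possible counts
of positive and negative real roots of the endemic quintic from its
coefficient signs, reproducing the published all-positive and alternating
rows and validated against a polynomial with known roots.

## Calibration

`fit_mle()` estimates $(\beta_1, \beta_2, \gamma_2)$ — the remaining rates
fixed — from a yearly case series by maximum likelihood. The default noise
model is Gaussian with constant variance profiled out in closed form
($\hat\sigma^2 = \mathrm{RSS}/n$, floored at $(10^{-8}\bar y)^2$ so perfect
fits return a finite value); a Poisson family sits behind a config switch.
For the Gaussian family the optimizer minimises a scaled RSS — the same
argmin as the profiled likelihood without the log's plateau — via
multi-start `L-BFGS-B` from a seeded Latin-hypercube scatter within the
bounds $(10^{-6}, 1]$, plus the literature values as a warm start. The
initial state is rebuilt from the data by a fixed rule: total population
$N_0$ from config, first-year cases split equally between $P$ and $D$,
saboteurs $1\%$ of $N_0$, $M = C = R = 0$. Wald intervals use the
Gauss–Newton observed information $J_r^\top J_r/\hat\sigma^2$ from a
central-difference residual Jacobian — positive semi-definite by
construction, unlike a doubly-differenced likelihood — truncated at the
bounds; non-invertible information yields `NA`, never a fabricated width.

The synthetic generator (`generate_prevalence_series()`) runs the model at
known rates from a fractions-based initial state and adds seeded noise
(Gaussian, $\mathrm{sd} = \mathrm{CV}\cdot\mathrm{signal}$, truncated at
zero — the truncation biases means upward only at high CV — or Poisson).
Its default scenario is deliberately coherent with the calibration rule
(same $B$ fraction, $M=C=R=0$, equal $P/D$ split), so the generating truth
is the exact maximiser of its own noise-free output; the noise-free round
trip recovers all three rates to well under 1%.

**What the generator does not emulate.** Real prevalence series carry
reporting changes, autocorrelated errors and demographic drift; none of
these are modelled, so passing recovery tests demonstrate internal
consistency of the estimator, not fidelity to the Spanish data, which the
package does not ship.

**Identifiability of $\gamma_2$.** Which compartments constitute a reported
"case" is genuinely unknown; the package offers `PD` (default,
$P+D$), `D`, and `PDMC` ($P+D+M+C$). Measured at the baseline: a $+10\%$
change in $\gamma_2$ moves the $P+D$ observable by $2.6\times10^{-5}$
relative — $\gamma_2$ touches $P+D$ only through the relapse loop — and the
$P+D+M+C$ observable by $1.1\times10^{-3}$, because $\gamma_2$ drains $C$
directly. The replicate studies therefore use `PDMC`, the only map under
which $\gamma_2$ carries usable information (the published tight $\gamma_2$
interval implies the original fit's observable was $\gamma_2$-sensitive
too). Even so, at 2% observation noise over 12 yearly points the
$\gamma_2$ signal is an order of magnitude below the noise: in replicate
studies $\beta_1$ and $\beta_2$ recover with median error of a few percent
and near-nominal Wald coverage, while $\gamma_2$'s estimate is
noise-driven (median error tens of percent, coverage below nominal — the
Wald ellipse degenerates where the estimate pins at a bound). This is a
statistical property of the design, not an optimizer failure; it is
reported as measured. Profile-likelihood intervals, which would repair the
coverage, are out of scope.

## Optimal control

Three bounded controls augment the treatment rates: $u_1$ adds to $\psi_1$
(finding and treating primary depression non-pharmacologically), $u_2$ to
$\psi_2$ (pharmacological uptake for secondary depression), $u_3$ to
$\gamma_2$ (enhanced treatment quality). The objective integrates
$W_1 P + W_2 D + W_3 M + W_4 C + \tfrac12(W_5 u_1^2 + W_6 u_2^2 + W_7 u_3^2)$
over a fixed horizon; defaults are the published weights ($W_{1..4} = 1$,
$W_5 = 15$, $W_6 = 40$, $W_7 = 55$), bounds $[0,1]$, horizon 15 years.

The adjoint system is computed as the exact gradient of the implemented
Hamiltonian, $\dot\Lambda = -\partial H/\partial x = -(J^\top\Lambda +
\nabla_x L)$ with the analytic Jacobian $J$ — not from the published
adjoint expressions, whose treatment-compartment rows repeat transmission
blocks that do not arise from differentiating the stated Hamiltonian. The
published system is retained verbatim in `adjoint_rhs_printed()` so the
discrepancy can be measured; agreement with a central-difference gradient
of the Hamiltonian to $10^{-6}$ relative is part of the test suite. The
pointwise minimiser is the projected stationarity condition
$u_1 = [(\Lambda_3-\Lambda_5)P/W_5]_{[a_1,b_1]}$ and analogously for
$u_2, u_3$ — verified against a dense grid search of the single-control
Hamiltonian restriction.

`forward_backward_sweep()` is the standard iterative scheme: forward RK4
for the states, backward RK4 for the adjoints from the transversality
condition $\Lambda(t_f) = 0$ (exact by construction), control update with
relaxation $u \leftarrow \tfrac12 u + \tfrac12 u^{\mathrm{new}}$, stopping
when the relative sup-norm control change falls below tolerance
($10^{-4}$ by default; the tests use $10^{-7}$ where pointwise
stationarity $|\partial H/\partial u| < 10^{-4}$ is asserted, since the
stationarity residual scales with $W_i$ times the last control change).
Default grid: 1501 nodes over 15 years; the analysis drivers and tests use
201–601 nodes, which changes objective values by well under the sweep
tolerance at these dynamics.

The strategy comparison runs the seven active-control masks A–G plus the
uncontrolled baseline on one grid. At the package's desk-scale scenario
(published rates, 10,000-person reference population, the generator's
default initial split — the original figures' initial conditions are not
public, so absolute counts are not comparable) the comprehensive strategy G
attains the lowest terminal $D$, and every two-control strategy beats both
of its single-control components in $J$. One instructive wrinkle: $u_3$
*alone* slightly raises terminal $D$ (and strategy F's terminal $D$ can
exceed A's by a hair) because accelerating $C \to R$ feeds the relapse flow
$\omega R \to D$ — the same structural route that makes horizon prevalence
weakly increasing in $\gamma_1, \gamma_2$ in the scenario sweeps, where the
narrative around the original figures expects a decrease. With $\omega = 0$
the dependence vanishes identically, which is how the property is tested.

A related consequence of the stable saboteur equilibrium: in scenario
comparisons, *removing* saboteurs ($\beta_1 = \lambda_1 = 0$) raises
long-run depression prevalence at the baseline rates, because the saboteur
class competes for susceptibles and its attractor is depression-free. The
qualitative narrative usually told about such models expects the opposite;
the scenario driver prints both numbers so the reader can see the mechanism
rather than the expectation.

## Scope and limitations

- Homogeneous mixing; no age, network or spatial structure; no demographic
  stochasticity.
- The published absolute strategy counts are not reproducible because their
  initial conditions are not stated; orderings and improvement properties
  are the tested substitutes.
- Symbolic Routh–Hurwitz conditions, global stability, bifurcation
  continuation, Sobol/PRCC global sensitivity, Bayesian or
  profile-likelihood inference, and cost-effectiveness analysis are out of
  scope.
- Problem sizes used by the shipped studies: 100-draw NGM checks, 1000-start
  positivity sweeps over 50 years, 20-replicate recovery and 100-replicate
  coverage studies, 201–601-node control grids — sizes at which every
  reported quantity is stable to well inside its test tolerance.
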