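# Baseline configuration: published literature/assumed rates together with
# the fitted contact and recovery rates. Lambda is a per-capita birth rate;
# set reference_population to work in absolute persons.
parameters:
  Lambda: 7.816e-4
  beta1: 0.5665
  beta2: 0.1567
  lambda1: 0.2145
  lambda2: 0.7
  psi1: 0.0045
  psi2: 0.02
  gamma1: 0.6
  gamma2: 0.9219
  sigma: 0.01
  omega: 0.005
  mu: 0.0125
reference_population: 1
initial_fractions: [0.94, 0.01, 0.025, 0.025, 0, 0, 0]
horizon: 15
control_weights:
  W1: 1
  W2: 1
  W3: 1
  W4: 1
  W5: 15
  W6: 40
  W7: 55
control_bounds:
  lower: [0, 0, 0]
  upper: [1, 1, 1]
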