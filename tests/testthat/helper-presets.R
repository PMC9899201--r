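# Shared fixtures: the two bundled presets and a small constant-interface
# parameter set used by the analytic-limit tests.

quadri <- tick_preset("quadri")
bi <- tick_preset("bi")

# constant scenario at a subcritical (R0 < 1) parameterisation
const_params_sub <- tick_params(delta = 0.033, eta = 45, tau = 700, T = 7,
                                p = 0.002, mu0 = 0.4)

# constant scenario exactly at criticality: eta * p = delta * exp(mu0 * T)
const_params_crit <- tick_params(delta = 0.033, eta = 45, tau = 700, T = 7,
                                 p = 0.033 * exp(0.4 * 7) / 45, mu0 = 0.4)

# dense sign-change scan used as the independent root-counting oracle;
# log-spaced grid so roots arbitrarily close to zero are still bracketed
scan_roots <- function(g, rhs, upper, n = 20000L) {
  x <- exp(seq(log(upper * 1e-14), log(upper), length.out = n))
  v <- g(x) - rhs
  sum(v[-n] * v[-1] < 0)
}
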