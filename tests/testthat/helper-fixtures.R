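# Small architectures and regimes shared across tests. Everything is
# generated in code under fixed seeds; no stored fixtures.

std_params <- function() {
  list(s = 0.1, N = 2e4, n = 200L, mu = 1e-5, mean_effect = 0.01, z0 = 0.2)
}

tiny_arch <- function(n = 5, seed = 11, mean_effect = 0.01, mu = 1e-5) {
  sample_architecture(n, mean_effect, mu, seed)
}

# Scalar-loop oracle for the trait cumulants: one locus at a time, no
# vectorization, used as the independent check of compute_cumulants().
cumulants_loop <- function(effects, p, optimum = 0) {
  c1 <- c2 <- c3 <- 0
  for (i in seq_along(effects)) {
    g <- effects[i]; pi <- p[i]; qi <- 1 - pi
    c1 <- c1 + g * (pi - qi)
    c2 <- c2 + 2 * g^2 * pi * qi
    c3 <- c3 + 2 * g^3 * pi * qi * (qi - pi)
  }
  list(c1 = c1, c2 = c2, c3 = c3, delta_c1 = c1 - optimum)
}

# Fixed-step Euler oracle for the deterministic dynamics.
euler_oracle <- function(arch, regime, p0, t_max, dt = 1e-3) {
  p <- p0
  steps <- round(t_max / dt)
  for (k in seq_len(steps)) {
    p <- p + dt * ode_rhs(p, arch, regime, (k - 1) * dt)
  }
  p
}
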