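test_that("ode_rhs reproduces hand-computed derivative and fixed points", {
  arch <- trait_architecture(0.01, 1e-5)
  reg <- selection_regime(0.1, 0.2)
  # single locus at p = 0.3: directional + stabilizing + mutation terms
  expect_equal(ode_rhs(0.3, arch, reg), 4.642e-5, tolerance = 1e-8)

  # all loci at 1/2 with the optimum at the (zero) mean: all terms vanish
  arch5 <- tiny_arch(5)
  reg0 <- selection_regime(0.1, 0, arch = arch5) |> suppressWarnings()
  expect_equal(ode_rhs(rep(0.5, 5), arch5, reg0), rep(0, 5))

  # absorbing boundaries without mutation
  arch_nomu <- trait_architecture(arch5$effects, 0)
  p <- c(0, 1, 0, 1, 0)
  expect_equal(ode_rhs(p, arch_nomu, reg0), rep(0, 5))
})

test_that("adaptive integration agrees with a fixed-step Euler oracle", {
  arch <- tiny_arch(5, seed = 2)
  reg <- selection_regime(0.1, 0.01, 0.03, shift_time = 0, arch = arch)
  p0 <- c(0.5, 0.4, 0.6, 0.5, 0.5)
  traj <- integrate_trajectory(arch, reg, p0, t_max = 100, dt = 100)
  p_euler <- euler_oracle(arch, reg, p0, t_max = 100, dt = 1e-3)
  expect_equal(unname(traj$freqs[nrow(traj$freqs), ]), p_euler,
               tolerance = 1e-4)
  expect_true(all(traj$freqs >= 0 & traj$freqs <= 1))
})

test_that("the pre-shift equilibrium is a fixed point of the dynamics", {
  arch <- sample_architecture(40, 0.02, 1e-5, seed = 8)
  reg <- selection_regime(0.1, 0.2, arch = arch)
  p0 <- equilibrium_frequencies(arch, reg)
  expect_true(all(p0[classify_loci(arch, reg$s) == "minor"] == 0.5))
  # major loci: mutation-selection balance p q = 2 mu / (s g^2)
  maj <- classify_loci(arch, reg$s) == "major"
  pq <- p0[maj] * (1 - p0[maj])
  expect_equal(pq, 2 * arch$mutation_rate / (reg$s * arch$effects[maj]^2),
               tolerance = 1e-9)

  # with the trait mean pinned at the optimum the state is stationary
  cs <- compute_cumulants(arch, p0)
  reg_at_mean <- suppressWarnings(selection_regime(reg$s, cs$c1))
  expect_lt(max(abs(ode_rhs(p0, arch, reg_at_mean))), 1e-12)
})

test_that("trajectory stays constant when started at the no-shift equilibrium", {
  arch <- sample_architecture(30, 0.01, 1e-4, seed = 3, minor_only = TRUE, s = 0.1)
  # minor loci start at exactly 1/2; with z0 > 0 the mean first relaxes to
  # its quasi-equilibrium near the optimum, after which the state is a
  # fixed point: continue integrating and require it not to move
  reg <- selection_regime(0.1, 0.05, arch = arch)
  p0 <- equilibrium_frequencies(arch, reg)
  traj0 <- integrate_trajectory(arch, reg, p0, t_max = 40000, dt = 1000)
  relaxed <- traj0$freqs[nrow(traj0$freqs), ]
  traj <- integrate_trajectory(arch, reg, relaxed, t_max = 2000, dt = 500)
  expect_lt(max(abs(sweep(traj$freqs, 2, relaxed))), 1e-5)
})

test_that("short-term rate formulas and scaling with locus number", {
  arch <- sample_architecture(200, 0.01, 1e-4, seed = 4, minor_only = TRUE, s = 0.1)
  reg <- selection_regime(0.1, 0.2, 0.4)
  expect_equal(short_term_rate(arch, reg, "small_effects"),
               0.1 * 200 * 0.01^2)
  expect_equal(short_term_rate(arch, reg, "large_effects"), 0.1 * 0.4 * 0.01)

  # doubling the number of minor loci doubles the small-effects rate
  arch2 <- sample_architecture(400, 0.01, 1e-4, seed = 4, minor_only = TRUE, s = 0.1)
  expect_equal(short_term_rate(arch2, reg, "small_effects"),
               2 * short_term_rate(arch, reg, "small_effects"))
})

test_that("quasi-equilibrium deviation follows the cumulant balance", {
  expect_equal(quasi_equilibrium_deviation(0.0123, 0, 1e-5, 0.1, 0.2),
               -4e-6 / 1.25e-3)
  expect_equal(quasi_equilibrium_deviation(0.01, 0, 0, 0.1, 0.2), 0)
  # mu = 0 limit: -c3 / (2 c2)
  expect_equal(quasi_equilibrium_deviation(0.01, -2e-5, 0, 0.1, 0.2),
               2e-5 / (2 * 0.01))
  expect_error(quasi_equilibrium_deviation(0, 0, 0, 0.1, 0.2), "> 0")
})

test_that("frequency-shift prediction: magnitude, sign coherence, boundaries", {
  one <- trait_architecture(0.01, 1e-5)
  ps <- predict_shifts(one, 0.5, delta_c1_0 = -0.2, c2_0 = 0.02)
  expect_equal(ps$delta_p, 0.01 * 0.25 * 0.2 * (1 - exp(-1)) / 0.02)
  expect_true(ps$aligned)

  arch <- tiny_arch(8, seed = 5)
  p0 <- runif(8)
  ps2 <- predict_shifts(arch, p0, -0.1, 0.01)
  expect_true(all(ps2$delta_p >= 0))
  expect_equal(predict_shifts(arch, p0, 0, 0.01)$delta_p, rep(0, 8))
  expect_equal(predict_shifts(arch, c(0, 1, 0, 1, 0, 1, 0, 1), -0.1, 0.01)$delta_p,
               rep(0, 8))
  expect_error(predict_shifts(arch, p0, -0.1, 0), "> 0")
})

test_that("sweep classification is monotone in effect size", {
  reg <- selection_regime(0.1, 0.2, 0.4)
  # small-effects-dominated: no sweeps when all effects below c2(0)
  small <- sample_architecture(200, 0.01, 1e-4, seed = 6, minor_only = TRUE, s = 0.1)
  p0 <- rep(0.5, 200)
  lab <- classify_sweep_candidates(small, reg, p0)
  c2_0 <- compute_cumulants(small, p0)$c2
  expect_true(all(lab[small$effects < c2_0] == "shift_expected"))

  # single large-effect locus (drawn from a small-mean distribution) sweeps
  big <- trait_architecture(0.1, 1e-5, mean_effect = 0.05)
  expect_equal(classify_sweep_candidates(big, reg, 0.05), "sweep_expected")

  # monotonicity within any architecture
  mixed <- sample_architecture(100, 0.03, 1e-5, seed = 7)
  labm <- classify_sweep_candidates(mixed, reg, rep(0.5, 100))
  if (any(labm == "sweep_expected") && any(labm == "shift_expected")) {
    expect_gt(min(mixed$effects[labm == "sweep_expected"]),
              max(mixed$effects[labm == "shift_expected"]))
  }
})

test_that("directional-only approximation tracks the full dynamics early on", {
  arch <- sample_architecture(200, 0.005, 1e-5, seed = 9, minor_only = TRUE, s = 0.1)
  reg <- selection_regime(0.1, 0.1, 0.3, shift_time = 0, arch = arch)
  p0 <- rep(0.5, 200)
  c2_0 <- compute_cumulants(arch, p0)$c2
  ts <- short_term_time(reg$s, c2_0)
  full <- integrate_trajectory(arch, reg, p0, t_max = ceiling(ts), dt = ceiling(ts) / 50)
  dironly <- integrate_trajectory(arch, reg, p0, t_max = ceiling(ts),
                                  dt = ceiling(ts) / 50, directional_only = TRUE)
  dev0 <- abs(full$cumulants$delta_c1[1])
  expect_lt(max(abs(full$cumulants$delta_c1 - dironly$cumulants$delta_c1)),
            0.05 * dev0)
})
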