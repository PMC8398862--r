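test_that("neutral single-generation update is a martingale with binomial variance", {
  arch <- trait_architecture(rep(0.01, 1), 0)
  reg <- suppressWarnings(selection_regime(1e-300, 0))
  # s effectively 0, mu = 0, N = 100: E[p'] = p, Var[p'] = p q / (2N)
  set.seed(101)
  draws <- replicate(2000, wf_step(0.3, arch, reg, N = 100))
  se_mean <- sqrt(0.3 * 0.7 / 200) / sqrt(2000)
  expect_lt(abs(mean(draws) - 0.3), 4 * se_mean)
  expect_lt(abs(var(draws) / (0.3 * 0.7 / 200) - 1), 0.15)
})

test_that("boundaries are absorbing without mutation and not with it", {
  arch <- trait_architecture(rep(0.02, 4), 0)
  reg <- selection_regime(0.1, 0.02)
  set.seed(5)
  p <- c(0, 1, 0, 1)
  for (k in 1:20) p <- wf_step(p, arch, reg, N = 50)
  expect_identical(p, c(0, 1, 0, 1))

  # with mu = 0 and s = 0, drift from the interior eventually absorbs
  arch0 <- trait_architecture(rep(0.02, 10), 0)
  reg0 <- suppressWarnings(selection_regime(1e-300, 0))
  set.seed(6)
  res <- wf_simulate(arch0, reg0, rep(0.5, 10), gens = 4000,
                     constant_demography(20), thin_cum = 0L)
  expect_true(all(res$p_final %in% c(0, 1)))
})

test_that("compiled engine reproduces the R-level step draw for draw", {
  arch <- tiny_arch(6, seed = 13)
  reg <- selection_regime(0.1, 0.02, arch = arch)
  p0 <- runif(6, 0.2, 0.8)
  set.seed(77)
  p_r <- wf_step(p0, arch, reg, N = 500, t = 0)
  set.seed(77)
  res <- wf_simulate(arch, reg, p0, gens = 1, constant_demography(500),
                     thin_cum = 0L)
  expect_identical(res$p_final, p_r)
})

test_that("simulations are bit-reproducible given seed and parameters", {
  arch <- tiny_arch(10, seed = 14)
  reg <- selection_regime(0.1, 0.03, arch = arch)
  run <- function() {
    set.seed(321)
    wf_simulate(arch, reg, rep(0.5, 10), gens = 300,
                constant_demography(200), thin_cum = 10L,
                thin_freq = 50L, record_loci = 1:10)
  }
  a <- run(); b <- run()
  expect_identical(a, b)
})

test_that("one large-N step matches the deterministic flow to O(1/sqrt(N))", {
  arch <- tiny_arch(5, seed = 15)
  reg <- selection_regime(0.1, 0.02, arch = arch)
  p0 <- c(0.3, 0.5, 0.7, 0.4, 0.6)
  det <- p0 + ode_rhs(p0, arch, reg, 0)
  set.seed(8)
  stoch <- wf_step(p0, arch, reg, N = 1e7)
  expect_equal(stoch, det, tolerance = 4 / sqrt(2e7) * 3)
})

test_that("demography schedules resolve sizes per generation", {
  d <- demography_schedule(c(0, 10, 30), c(100, 20, 100))
  sizes <- demography_sizes(d, 40)
  expect_identical(sizes[1:10], rep(100L, 10))
  expect_identical(sizes[11:30], rep(20L, 20))
  expect_identical(sizes[31:40], rep(100L, 10))
  expect_error(demography_schedule(c(5, 10), c(10, 10)), "start at generation 0")
  expect_error(demography_schedule(c(0, 0), c(10, 10)), "strictly increasing")
})

test_that("neutral stationary distribution matches the mutation-drift beta law", {
  # gamma -> 0 limit of the stationary density: Beta(2*beta, 2*beta).
  # Small population for fast mixing; loci are independent when s ~ 0, so
  # pooling across loci and widely spaced time slices gives an effectively
  # independent sample.
  N <- 500; mu <- 2e-4; beta <- 2 * N * mu  # beta = 0.2
  arch <- trait_architecture(rep(0.01, 50), mu)
  reg <- suppressWarnings(selection_regime(1e-300, 0))
  set.seed(2024)
  pool <- c()
  for (r in 1:10) {
    bi <- wf_simulate(arch, reg, runif(50), gens = 8000,
                      constant_demography(N), thin_cum = 0L)
    sm <- wf_simulate(arch, reg, bi$p_final, gens = 20000,
                      constant_demography(N), thin_cum = 0L,
                      thin_freq = 5000L, record_loci = 1:50)
    pool <- c(pool, as.numeric(sm$freq))
  }
  # exclude monomorphic states: the diffusion density describes the interior
  interior <- pool[pool > 0 & pool < 1]
  expect_gt(length(interior), 500)
  # chi-square against Beta(0.4, 0.4) probabilities, interior-renormalized
  breaks <- seq(0, 1, by = 0.1)
  obs <- tabulate(findInterval(interior, breaks, rightmost.closed = TRUE), 10)
  pr <- diff(pbeta(breaks, 2 * beta, 2 * beta))
  gof <- suppressWarnings(chisq.test(obs, p = pr / sum(pr)))
  # autocorrelation between pooled slices is weak but nonzero: require no
  # gross deviation rather than a calibrated p-value
  expect_gt(gof$p.value, 1e-4)
  tv <- tv_distance(obs / sum(obs), pr / sum(pr))
  expect_lt(tv, 0.08)
})

test_that("shift experiment: null shift gives no coherent frequency change", {
  arch <- sample_architecture(30, 0.01, 1e-4, seed = 17, minor_only = TRUE, s = 0.1)
  reg <- selection_regime(0.1, 0.05, 0.05, shift_time = 0, arch = arch)
  res <- run_shift_experiment(arch, reg, constant_demography(500),
                              burn_in_gens = 500, post_shift_gens = 400,
                              replicates = 30, seed = 4)
  mdp <- colMeans(res$delta_p)
  se <- apply(res$delta_p, 2, sd) / sqrt(nrow(res$delta_p))
  # mean shift indistinguishable from zero at nearly all loci
  expect_lt(mean(abs(mdp) > 4 * se), 0.1)
})

test_that("replicate seeds derive deterministically from the master seed", {
  expect_identical(polytrait:::replicate_seeds(99, 5),
                   polytrait:::replicate_seeds(99, 5))
  expect_false(any(polytrait:::replicate_seeds(99, 5) ==
                     polytrait:::replicate_seeds(100, 5)))
})
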