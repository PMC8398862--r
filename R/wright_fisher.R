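#' Demography schedule
#'
#' An ordered list of epochs `(start_generation, N)`; the population size in
#' generation `t` (0-based) is the `N` of the last epoch starting at or
#' before `t`. The first epoch must start at generation 0.
#'
#' @param starts integer vector of strictly increasing epoch start
#'   generations, beginning with 0.
#' @param sizes positive integer diploid population sizes, one per epoch.
#' @return An object of class `demography_schedule`.
#' @export
demography_schedule <- function(starts, sizes) {
  starts <- as.integer(starts)
  sizes <- as.integer(sizes)
  if (length(starts) != length(sizes)) stop("starts and sizes lengths differ")
  if (starts[1] != 0L) stop("first epoch must start at generation 0")
  if (any(diff(starts) <= 0)) stop("epoch starts must be strictly increasing")
  if (any(sizes < 1L)) stop("population sizes must be >= 1")
  structure(list(starts = starts, sizes = sizes), class = "demography_schedule")
}

#' Constant-size demography
#' @param N diploid population size.
#' @return A [demography_schedule()] with a single epoch.
#' @export
constant_demography <- function(N) demography_schedule(0L, N)

#' Population size per generation
#' @param demography a [demography_schedule()].
#' @param gens number of generations.
#' @return Integer vector of length `gens` with the size in each generation
#'   (0-based generations `0 .. gens - 1`).
#' @export
demography_sizes <- function(demography, gens) {
  idx <- findInterval(seq_len(gens) - 1L, demography$starts)
  demography$sizes[idx]
}

#' One Wright-Fisher generation
#'
#' The deterministic expectation of the next frequency is computed per locus
#' from [ode_rhs()] applied over one generation (with the trait-mean
#' deviation evaluated from the full current frequency vector and the
#' current optimum), clipped to \[0, 1\], and the realized next frequency is
#' drawn as `Binomial(2N, p*) / 2N`, independently per locus since the loci
#' are unlinked.
#'
#' This R-level step is convenient for small studies and tests; long runs
#' should use [wf_simulate()], which performs the identical update in
#' compiled code (and draws identical values for the same RNG state).
#'
#' @param freqs current "+"-allele frequencies.
#' @param arch a [trait_architecture()].
#' @param regime a [selection_regime()].
#' @param N diploid population size this generation.
#' @param t current generation (resolves the optimum).
#' @return Vector of next-generation frequencies.
#' @export
wf_step <- function(freqs, arch, regime, N, t = 0) {
  ep <- freqs + ode_rhs(freqs, arch, regime, t)
  ep <- pmin(pmax(ep, 0), 1)
  rbinom(length(ep), 2 * N, ep) / (2 * N)
}

#' Simulate the finite-population model
#'
#' Runs the per-locus binomial Wright-Fisher dynamics for `gens`
#' generations under a [selection_regime()] (whose optimum may shift) and a
#' [demography_schedule()]. States after generation `g` are recorded
#' whenever `g` is a multiple of the corresponding thinning interval.
#'
#' @param arch a [trait_architecture()].
#' @param regime a [selection_regime()].
#' @param p0 initial frequencies.
#' @param gens number of generations to simulate.
#' @param demography a [demography_schedule()].
#' @param thin_cum recording interval for the trait cumulants (0 = none).
#' @param thin_freq recording interval for per-locus frequencies (0 = none).
#' @param record_loci indices of loci whose frequencies are recorded.
#' @param t0 generation index of the first simulated generation (so that a
#'   regime shift scheduled in absolute time is honoured when simulating in
#'   segments).
#' @return A list with `p_final`, cumulant series (`t_cum`, `c1`, `c2`,
#'   `c3`), and recorded frequencies (`t_freq`, `freq`). Recorded times are
#'   offset by `t0`.
#' @export
wf_simulate <- function(arch, regime, p0, gens, demography,
                        thin_cum = 10L, thin_freq = 0L,
                        record_loci = integer(0), t0 = 0) {
  if (length(p0) != arch$n_loci) stop("p0 must have one entry per locus")
  if (any(p0 < 0 | p0 > 1)) stop("initial frequencies must lie in [0, 1]")
  gens <- as.integer(gens)
  if (gens < 1L) stop("gens must be >= 1")
  opt <- optimum_at(regime, t0 + seq_len(gens) - 1L)
  N <- demography$sizes[findInterval(t0 + seq_len(gens) - 1L, demography$starts)]
  res <- wf_run_cpp(p0, arch$effects, regime$s, arch$mutation_rate,
                    opt, as.integer(N),
                    as.integer(thin_cum), as.integer(thin_freq),
                    as.integer(record_loci))
  res$t_cum <- res$t_cum + t0
  res$t_freq <- res$t_freq + t0
  res$delta_c1 <- res$c1 - optimum_at(regime, res$t_cum)
  res
}

#' Burn a population in to its stochastic equilibrium
#'
#' Iterates the Wright-Fisher dynamics with the optimum fixed at
#' `optimum_before`. The default length is `3 N` generations (with `N` the
#' size of the first epoch); longer burn-ins can be requested when the
#' initial state is far from stationarity. A simple stationarity diagnostic
#' compares the time-averaged genetic variance over the first and second
#' halves of the burn-in.
#'
#' @inheritParams wf_simulate
#' @param generations burn-in length; default `3 * N`.
#' @param p0 initial frequencies; default is the deterministic equilibrium
#'   ([equilibrium_frequencies()]).
#' @return A list with `freqs` (final state), `diagnostic` (relative
#'   difference of half-window mean `c2`), and the recorded cumulant series.
#' @export
burn_in <- function(arch, regime, demography, generations = NULL, p0 = NULL,
                    thin_cum = 10L) {
  if (is.null(generations)) generations <- 3L * demography$sizes[1]
  if (is.null(p0)) p0 <- equilibrium_frequencies(arch, regime)
  reg0 <- selection_regime(regime$s, regime$optimum_before)
  res <- wf_simulate(arch, reg0, p0, generations, demography,
                     thin_cum = thin_cum)
  h <- length(res$c2) %/% 2
  diag <- if (h >= 1) {
    m1 <- mean(res$c2[seq_len(h)])
    m2 <- mean(res$c2[(h + 1):length(res$c2)])
    (m2 - m1) / ((m1 + m2) / 2)
  } else NA_real_
  list(freqs = res$p_final, diagnostic = diag,
       t_cum = res$t_cum, c1 = res$c1, c2 = res$c2, c3 = res$c3,
       delta_c1 = res$c1 - regime$optimum_before)
}

# Deterministic replicate-seed rule: a master seed expands to one
# sub-stream seed per replicate by drawing from the master-seeded RNG.
replicate_seeds <- function(master_seed, n) {
  withr_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Optimum-shift experiment
#'
#' For each replicate: burn in at `optimum_before`, shift the optimum to
#' `optimum_after`, and record the ensemble response. Per-locus frequency
#' shifts `delta_p` are measured at the end of the short-term phase,
#' `t* = 1 / (s * c2(0))` generations after the shift, with `c2(0)` the
#' replicate's variance at shift time.
#'
#' @inheritParams wf_simulate
#' @param burn_in_gens burn-in length (default `3 N`).
#' @param post_shift_gens generations simulated after the shift; default
#'   `2 t*` based on the expected equilibrium variance.
#' @param replicates number of independent replicates.
#' @param seed master seed; replicate seeds are derived from it by a fixed
#'   rule, making the whole experiment reproducible.
#' @param thin_cum recording interval for cumulants after the shift.
#' @return An object of class `shift_result`: `times` (post-shift), matrix
#'   `delta_c1` (replicates x times), `delta_p` (replicates x loci) at
#'   `t_star`, `p_at_shift`, `c2_at_shift`, `t_star`, `params`.
#' @export
run_shift_experiment <- function(arch, regime, demography,
                                 burn_in_gens = NULL, post_shift_gens = NULL,
                                 replicates = 20L, seed = 1L, thin_cum = 10L) {
  seeds <- replicate_seeds(seed, replicates)
  n <- arch$n_loci
  dc1 <- NULL
  dp <- matrix(NA_real_, replicates, n)
  p_shift <- matrix(NA_real_, replicates, n)
  c2_shift <- numeric(replicates)
  t_star <- numeric(replicates)
  times <- NULL
  for (r in seq_len(replicates)) {
    set.seed(seeds[r])
    bi <- burn_in(arch, regime, demography, generations = burn_in_gens)
    c2_0 <- compute_cumulants(arch, bi$freqs)$c2
    ts <- short_term_time(regime$s, c2_0)
    gens <- if (is.null(post_shift_gens)) ceiling(2 * ts) else post_shift_gens
    reg1 <- selection_regime(regime$s, regime$optimum_after)
    # ~10 frequency snapshots up to t*, capped by the simulated horizon
    thin_freq <- max(1L, min(as.integer(ceiling(ts / 10)), as.integer(gens)))
    res <- wf_simulate(arch, reg1, bi$freqs, gens, demography,
                       thin_cum = thin_cum, thin_freq = thin_freq,
                       record_loci = seq_len(n))
    # frequency snapshot closest to t*
    k <- which.min(abs(res$t_freq - ts))
    dp[r, ] <- res$freq[k, ] - bi$freqs
    p_shift[r, ] <- bi$freqs
    c2_shift[r] <- c2_0
    t_star[r] <- ts
    if (is.null(times)) {
      times <- res$t_cum
      dc1 <- matrix(NA_real_, replicates, length(times))
    }
    dc1[r, ] <- res$c1 - regime$optimum_after
  }
  structure(list(times = times, delta_c1 = dc1, delta_p = dp,
                 p_at_shift = p_shift, c2_at_shift = c2_shift,
                 t_star = t_star, seed = seed,
                 params = list(arch = arch, regime = regime,
                               demography = demography,
                               replicates = replicates)),
            class = "shift_result")
}

#' Bottleneck experiment
#'
#' Burn in at the base size with the optimum fixed, then reduce the
#' population to `N_bottleneck` for `bottleneck_gens` generations. Reported
#' are the percent changes, from the pre-bottleneck stationary baseline to
#' the end of the bottleneck, of (a) the magnitude of the quasi-equilibrium
#' deviation of the trait mean from the optimum and (b) the genetic
#' variance `c2`.
#'
#' Measurement protocol: the baseline pools the last `baseline_window`
#' generations of burn-in across replicates; the end state pools the final
#' `end_window` generations of the bottleneck across replicates. The
#' genetic variance is the pooled average of `c2`; the deviation is the
#' pooled average of `|delta_c1|`. Note what the absolute deviation
#' measures in this regime: the instantaneous deviation fluctuates around
#' its small quasi-equilibrium mean with standard deviation of order
#' `1/sqrt(2 N s)` (0.016 at the default base size, 0.041 during the
#' default bottleneck), which dominates `|delta_c1|`; its increase under a
#' bottleneck therefore mainly tracks the amplified drift fluctuations of
#' the trait mean, roughly as `sqrt(N_base / N_bottleneck)`. The
#' quasi-equilibrium deviations implied by the pooled cumulants
#' ([quasi_equilibrium_deviation()]) and the (noisy) signed ensemble means
#' are returned alongside as diagnostics; the signed mean needs far more
#' replication than its absolute counterpart, and the quasi-equilibrium
#' value is a near-cancellation of the skew and mutation terms whose
#' relative change is ill-conditioned.
#'
#' The default burn-in is `8 N` generations: per-locus allele frequencies
#' relax toward stationarity over order-`2 N` generations, so a stationary
#' baseline needs a burn-in of several multiples of that (the [burn_in()]
#' stationarity diagnostic can be used to verify); percent changes measured
#' against a still-relaxing baseline would conflate the bottleneck response
#' with the remaining transient.
#'
#' @inheritParams run_shift_experiment
#' @param N_base pre-bottleneck diploid size.
#' @param N_bottleneck size during the bottleneck (< `N_base`).
#' @param bottleneck_gens bottleneck duration in generations.
#' @param baseline_window,end_window averaging windows (generations).
#' @return An object of class `bottleneck_result` with
#'   `mean_dev_change_pct`, `variance_change_pct`, the underlying baseline /
#'   end-state summaries (pooled `c2`, `c3`, quasi-equilibrium and directly
#'   measured deviations), and the ensemble-mean `c2(t)` trajectory during
#'   the bottleneck.
#' @export
run_bottleneck_experiment <- function(arch, regime, N_base, N_bottleneck,
                                      bottleneck_gens = 5000L,
                                      replicates = 100L, seed = 1L,
                                      burn_in_gens = NULL,
                                      baseline_window = 2000L,
                                      end_window = 1000L, thin_cum = 10L) {
  if (N_bottleneck >= N_base) stop("N_bottleneck must be < N_base")
  if (is.null(burn_in_gens)) burn_in_gens <- 8L * as.integer(N_base)
  seeds <- replicate_seeds(seed, replicates)
  base_dc1 <- base_abs <- base_c2 <- base_c3 <- numeric(replicates)
  end_dc1 <- end_abs <- end_c2 <- end_c3 <- numeric(replicates)
  c2_traj <- NULL
  for (r in seq_len(replicates)) {
    set.seed(seeds[r])
    bi <- burn_in(arch, regime, constant_demography(N_base),
                  generations = burn_in_gens, thin_cum = thin_cum)
    keep <- bi$t_cum > burn_in_gens - baseline_window
    base_dc1[r] <- mean(bi$delta_c1[keep])
    base_abs[r] <- mean(abs(bi$delta_c1[keep]))
    base_c2[r] <- mean(bi$c2[keep])
    base_c3[r] <- mean(bi$c3[keep])
    reg0 <- selection_regime(regime$s, regime$optimum_before)
    res <- wf_simulate(arch, reg0, bi$freqs, bottleneck_gens,
                       constant_demography(N_bottleneck), thin_cum = thin_cum)
    keep2 <- res$t_cum > bottleneck_gens - end_window
    end_dc1[r] <- mean(res$delta_c1[keep2])
    end_abs[r] <- mean(abs(res$delta_c1[keep2]))
    end_c2[r] <- mean(res$c2[keep2])
    end_c3[r] <- mean(res$c3[keep2])
    if (is.null(c2_traj)) c2_traj <- matrix(NA_real_, replicates, length(res$c2))
    c2_traj[r, ] <- res$c2
    times <- res$t_cum
  }
  mu <- arch$mutation_rate
  z0 <- regime$optimum_before
  qdev0 <- quasi_equilibrium_deviation(mean(base_c2), mean(base_c3),
                                       mu, regime$s, z0)
  qdev1 <- quasi_equilibrium_deviation(mean(end_c2), mean(end_c3),
                                       mu, regime$s, z0)
  structure(list(
    mean_dev_change_pct = 100 * (mean(end_abs) - mean(base_abs)) / mean(base_abs),
    variance_change_pct = 100 * (mean(end_c2) - mean(base_c2)) / mean(base_c2),
    baseline = list(abs_dev = mean(base_abs), quasi_eq_dev = qdev0,
                    measured_dev = mean(base_dc1),
                    c2 = mean(base_c2), c3 = mean(base_c3)),
    end_state = list(abs_dev = mean(end_abs), quasi_eq_dev = qdev1,
                     measured_dev = mean(end_dc1),
                     c2 = mean(end_c2), c3 = mean(end_c3)),
    times = times, c2_mean_trajectory = colMeans(c2_traj),
    seed = seed,
    params = list(arch = arch, regime = regime, N_base = N_base,
                  N_bottleneck = N_bottleneck,
                  bottleneck_gens = bottleneck_gens,
                  replicates = replicates, burn_in_gens = burn_in_gens)),
    class = "bottleneck_result")
}
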