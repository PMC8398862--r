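#' Total-variation distance between binned distributions
#'
#' @param p,q probability vectors over the same bins (renormalized).
#' @return `0.5 * sum(|p - q|)` in \[0, 1\].
#' @export
tv_distance <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  0.5 * sum(abs(p / sum(p) - q / sum(q)))
}

#' Experiment configuration
#'
#' A named parameter block that round-trips losslessly through YAML or JSON
#' and is embedded in every experiment report, so any run can be reproduced
#' from its own output.
#'
#' @param experiment experiment name.
#' @param ... parameter overrides (see the individual experiment drivers
#'   for their defaults).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment, ...) {
  structure(c(list(experiment = experiment), list(...)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config an `experiment_config`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path) else yaml::read_yaml(path)
  do.call(experiment_config, c(list(experiment = x$experiment),
                               x[setdiff(names(x), "experiment")]))
}

# Shared defaults: the standard parameter set used throughout the
# equilibrium and bottleneck studies (values from the human polygenic
# adaptation literature).
standard_params <- function() {
  list(s = 0.1, N = 2e4, n = 200L, mu = 1e-5, mean_effect = 0.01, z0 = 0.2)
}

#' Equilibrium-distribution experiment
#'
#' Simulates the standard parameter set to stochastic equilibrium and
#' compares the simulated allele-frequency distribution with the
#' diffusion-theory stationary density. A focal locus with effect size
#' `focal_gamma` is pinned into the sampled architecture (replacing the
#' nearest sampled effect) so the single-locus comparison is like-for-like.
#'
#' Two pooling modes are provided. `"all_loci"` (default) pools the
#' frequencies of every locus across time samples and replicates and
#' compares them against the corresponding mixture of per-locus stationary
#' densities; because the loci are coupled only weakly (through the trait
#' mean), this multiplies the effective sample size by roughly the number
#' of loci and is the statistically efficient test of the theory.
#' `"focal"` pools only the focal locus, the single-locus protocol; note
#' that per-locus frequencies decorrelate only over order-2N generations,
#' so this mode needs far longer runs for the same precision.
#'
#' @param config optional [experiment_config()]; entries override the
#'   defaults below.
#' @param seed master seed.
#' @param replicates independent replicates (independent architectures are
#'   NOT resampled; the architecture is fixed by `seed` so the theory
#'   mixture is like-for-like).
#' @param burn_in_gens burn-in length (default `3 N`).
#' @param sample_gens post-burn-in sampling window.
#' @param thin sampling interval within the window (generations).
#' @param pool `"all_loci"` or `"focal"`.
#' @param delta_c1_mode `"measured"` (time-averaged deviation from the run
#'   itself, default) or `"eq9"` (quasi-equilibrium fixed point evaluated
#'   from the measured variance and skew).
#' @param breaks histogram bin boundaries (default 20 equal bins).
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return A report list: measured `delta_c1_tilde`, time-averaged `c2`,
#'   `c3`, histogram and theory bin probabilities, `tv` (total-variation
#'   distance), `shape` checks, and the resolved configuration.
#' @export
experiment_figure1 <- function(config = NULL, seed = 1L, replicates = 3L,
                               burn_in_gens = NULL, sample_gens = 2e5,
                               thin = 25L, pool = c("all_loci", "focal"),
                               delta_c1_mode = c("measured", "eq9"),
                               breaks = seq(0, 1, by = 0.05), out_dir = NULL,
                               focal_gamma = 0.0107, params = standard_params()) {
  pool <- match.arg(pool)
  delta_c1_mode <- match.arg(delta_c1_mode)
  if (!is.null(config)) {
    ov <- unclass(config)
    ov$experiment <- NULL
    for (nm in names(ov)) assign(nm, ov[[nm]])
  }
  pp <- params
  if (is.null(burn_in_gens)) burn_in_gens <- 3L * as.integer(pp$N)

  arch <- sample_architecture(pp$n, pp$mean_effect, pp$mu, seed)
  focal <- which.min(abs(arch$effects - focal_gamma))
  arch$effects[focal] <- focal_gamma
  regime <- selection_regime(pp$s, pp$z0, arch = arch)
  demo <- constant_demography(pp$N)
  seeds <- replicate_seeds(seed, replicates)

  freqs <- list(); dc1 <- c2 <- c3 <- numeric(0)
  for (r in seq_len(replicates)) {
    set.seed(seeds[r])
    bi <- burn_in(arch, regime, demo, generations = burn_in_gens)
    res <- wf_simulate(arch, regime, bi$freqs, sample_gens, demo,
                       thin_cum = as.integer(thin), thin_freq = as.integer(thin),
                       record_loci = if (pool == "focal") focal else seq_len(pp$n))
    freqs[[r]] <- res$freq
    dc1 <- c(dc1, res$delta_c1); c2 <- c(c2, res$c2); c3 <- c(c3, res$c3)
  }
  pooled <- unlist(freqs)
  dct_measured <- mean(dc1)
  c2_bar <- mean(c2); c3_bar <- mean(c3)
  dct <- if (delta_c1_mode == "measured") dct_measured else
    quasi_equilibrium_deviation(c2_bar, c3_bar, pp$mu, pp$s, pp$z0)

  hist_p <- bin_props(pooled, breaks)
  gammas <- if (pool == "focal") focal_gamma else arch$effects
  theo <- theory_bin_mixture(gammas, pp, dct, breaks)
  dens_focal <- stationary_density(
    diffusion_params(pp$N, pp$s, pp$mu, focal_gamma, dct))

  report <- list(
    delta_c1_tilde = dct_measured, delta_c1_eq9 =
      quasi_equilibrium_deviation(c2_bar, c3_bar, pp$mu, pp$s, pp$z0),
    c2 = c2_bar, c3 = c3_bar,
    breaks = breaks, hist = hist_p, theory = theo,
    tv = tv_distance(hist_p, theo),
    shape = dens_focal$shape,
    u_shaped_theory = dens_focal$density(1e-3) > dens_focal$density(0.5),
    n_pooled = length(pooled), pool = pool, focal_locus = focal,
    focal_gamma = focal_gamma,
    config = list(seed = seed, replicates = replicates,
                  burn_in_gens = burn_in_gens, sample_gens = sample_gens,
                  thin = thin, pool = pool, delta_c1_mode = delta_c1_mode,
                  focal_gamma = focal_gamma, params = pp))
  if (!is.null(out_dir)) write_figure1_outputs(report, dens_focal, out_dir)
  report
}

bin_props <- function(x, breaks) {
  # interior frequencies fall in (0,1); boundary values are assigned to the
  # end bins
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              length(breaks) - 1L)
  tabulate(idx, nbins = length(breaks) - 1L) / length(x)
}

theory_bin_mixture <- function(gammas, pp, dct, breaks) {
  probs <- vapply(gammas, function(g) {
    stationary_bin_probs(diffusion_params(pp$N, pp$s, pp$mu, g, dct), breaks)
  }, numeric(length(breaks) - 1L))
  rowMeans(probs)
}

write_figure1_outputs <- function(report, dens_focal, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mid <- (report$breaks[-1] + report$breaks[-length(report$breaks)]) / 2
  write_tsv(data.frame(bin_mid = mid, simulated = report$hist,
                       theory = report$theory),
            file.path(out_dir, "histogram.tsv"))
  grid <- seq(0.001, 0.999, length.out = 399)
  write_tsv(data.frame(p = grid, density = dens_focal$density(grid)),
            file.path(out_dir, "density.tsv"))
  jsonlite::write_json(report[c("delta_c1_tilde", "delta_c1_eq9", "c2", "c3",
                                "tv", "shape", "n_pooled", "config")],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bottleneck experiment with theory companions
#'
#' Runs [run_bottleneck_experiment()] at the standard parameters (base size
#' 2e4 reduced to 3000 for 5000 generations by default) and attaches the
#' theoretical companions: the quasi-equilibrium prediction of the mean
#' deviation from the measured end-of-bottleneck variance and skew, and the
#' drift-driven variance decay from the moment dynamics.
#'
#' @inheritParams experiment_figure1
#' @param N_bottleneck,bottleneck_gens bottleneck severity and duration.
#' @param replicates independent replicates.
#' @return Report list: `mean_dev_change_pct`, `variance_change_pct`,
#'   baseline and end-state summaries, theory companions, configuration.
#' @export
experiment_bottleneck <- function(config = NULL, seed = 1L, replicates = 100L,
                                  N_bottleneck = 3000L, bottleneck_gens = 5000L,
                                  burn_in_gens = NULL, out_dir = NULL,
                                  params = standard_params()) {
  if (!is.null(config)) {
    ov <- unclass(config); ov$experiment <- NULL
    for (nm in names(ov)) assign(nm, ov[[nm]])
  }
  pp <- params
  arch <- sample_architecture(pp$n, pp$mean_effect, pp$mu, seed)
  regime <- selection_regime(pp$s, pp$z0, arch = arch)
  res <- run_bottleneck_experiment(arch, regime, N_base = pp$N,
                                   N_bottleneck = N_bottleneck,
                                   bottleneck_gens = bottleneck_gens,
                                   replicates = replicates, seed = seed,
                                   burn_in_gens = burn_in_gens)
  # theory companion: drift-driven decay of the variance contribution of an
  # average locus (directional field ~ 0 at the optimum). Initial E[pq]
  # reproduces the measured baseline variance via c2 = 2 sum(g^2) E[pq].
  het0 <- res$baseline$c2 / (2 * sum(arch$effects^2))
  mom <- integrate_moments(pp$mean_effect, pp$s, N_bottleneck,
                           m1_0 = 0.5, m2_0 = 0.5 - het0,
                           delta_c1_fun = function(t) 0,
                           t_max = bottleneck_gens, dt = 50)
  report <- list(
    mean_dev_change_pct = res$mean_dev_change_pct,
    variance_change_pct = res$variance_change_pct,
    baseline = res$baseline, end_state = res$end_state,
    c2_trajectory = data.frame(time = res$times, c2 = res$c2_mean_trajectory),
    moment_ode = mom,
    config = list(seed = seed, replicates = replicates,
                  N_bottleneck = N_bottleneck,
                  bottleneck_gens = bottleneck_gens, params = pp))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(report$c2_trajectory, file.path(out_dir, "c2_trajectory.tsv"))
    jsonlite::write_json(report[c("mean_dev_change_pct", "variance_change_pct",
                                  "baseline", "end_state", "config")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Adaptation-regime comparison
#'
#' For each architecture in a small-, mixed- and large-effects panel, runs
#' the deterministic optimum-shift dynamics from the pre-shift equilibrium,
#' fits the exponential approach rate of the trait mean, and counts loci
#' whose "+"-allele frequency crosses `sweep_threshold` within the
#' short-term phase (sweeps).
#'
#' @inheritParams experiment_figure1
#' @param architectures named list of [trait_architecture()] objects; the
#'   default panel holds a minor-only architecture, the standard
#'   exponential one, and a large-mean-effect one dominated by major loci.
#' @param z0,zf optimum before and after the shift.
#' @param sweep_threshold frequency defining a (near-)fixation.
#' @return A data.frame with one row per architecture: fitted rate, the
#'   small-effects analytical rate, sweep count and locus counts.
#' @export
experiment_regimes <- function(config = NULL, seed = 1L, architectures = NULL,
                               z0 = 0.2, zf = 0.4, s = 0.1, mu = 1e-5,
                               sweep_threshold = 0.95,
                               params = standard_params()) {
  if (!is.null(config)) {
    ov <- unclass(config); ov$experiment <- NULL
    for (nm in names(ov)) assign(nm, ov[[nm]])
  }
  if (is.null(architectures)) {
    architectures <- list(
      small = sample_architecture(params$n, params$mean_effect, mu, seed,
                                  minor_only = TRUE, s = s),
      mixed = sample_architecture(params$n, params$mean_effect, mu, seed + 1L),
      large = sample_architecture(20L, 0.06, mu, seed + 2L))
  }
  rows <- lapply(names(architectures), function(nm) {
    arch <- architectures[[nm]]
    regime <- selection_regime(s, z0, zf, shift_time = 0)
    p0 <- equilibrium_frequencies(arch, regime)
    c2_0 <- compute_cumulants(arch, p0)$c2
    ts <- short_term_time(s, c2_0)
    traj <- integrate_trajectory(arch, regime, p0, t_max = ceiling(4 * ts),
                                 dt = max(1, round(ts / 200)), fit_rate = TRUE)
    sweeps <- sum(apply(traj$freqs[traj$times <= ts, , drop = FALSE] >=
                          sweep_threshold, 2, any) & p0 < sweep_threshold)
    data.frame(architecture = nm, n_loci = arch$n_loci,
               n_major = sum(classify_loci(arch, s) == "major"),
               fitted_rate = traj$rate_estimate,
               small_effects_rate = short_term_rate(arch,
                 selection_regime(s, z0, zf), "small_effects"),
               t_star = ts, sweep_count = sweeps)
  })
  do.call(rbind, rows)
}
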