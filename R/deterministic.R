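#' Right-hand side of the deterministic allele-frequency dynamics
#'
#' In an effectively infinite population, the "+"-allele frequency at locus
#' `i` obeys
#' \deqn{dp_i/dt = -s \gamma_i p_i q_i \Delta c_1
#'   - (s \gamma_i^2 / 2) p_i q_i (q_i - p_i) + \mu (q_i - p_i),}
#' where `delta_c1 = c1 - z_opt(t)` couples all loci through the trait mean.
#' The three terms are directional selection toward the optimum, stabilizing
#' selection around it, and symmetric mutation.
#'
#' @param freqs current "+"-allele frequencies.
#' @param arch a [trait_architecture()].
#' @param regime a [selection_regime()].
#' @param t generation (resolves the current optimum).
#' @param directional_only if `TRUE`, keep only the directional term - the
#'   short-term approximation valid while the population is far from the
#'   optimum.
#' @return Vector of time derivatives `dp/dt`.
#' @export
ode_rhs <- function(freqs, arch, regime, t = 0, directional_only = FALSE) {
  g <- arch$effects
  q <- 1 - freqs
  pq <- freqs * q
  dc1 <- sum(g * (2 * freqs - 1)) - optimum_at(regime, t)
  d <- -regime$s * g * pq * dc1
  if (!directional_only)
    d <- d - (regime$s * g^2 / 2) * pq * (q - freqs) +
      arch$mutation_rate * (q - freqs)
  d
}

#' Integrate the deterministic dynamics
#'
#' Solves the coupled system with `deSolve::ode` (lsoda, relative tolerance
#' `1e-8`). Frequencies are checked at every output time; overshoots beyond
#' \[0, 1\] larger than `1e-12` trigger a retry with tighter tolerances,
#' smaller ones are clipped.
#'
#' @inheritParams ode_rhs
#' @param p0 initial frequencies.
#' @param t_max final generation.
#' @param dt output interval (generations).
#' @param fit_rate if `TRUE`, attach the fitted exponential decay rate of
#'   `|delta_c1(t)|` after the optimum shift (see [fit_decay_rate()]).
#' @return An object of class `det_trajectory`: `times`, `freqs` (times x
#'   n matrix), `cumulants` (data.frame with `c1`, `c2`, `c3`, `delta_c1`)
#'   and optionally `rate_estimate`.
#' @export
integrate_trajectory <- function(arch, regime, p0, t_max, dt = 1,
                                 directional_only = FALSE, fit_rate = FALSE) {
  if (length(p0) != arch$n_loci) stop("p0 must have one entry per locus")
  if (any(p0 < 0 | p0 > 1)) stop("initial frequencies must lie in [0, 1]")
  times <- seq(0, t_max, by = dt)
  deriv <- function(t, y, parms)
    list(ode_rhs(y, arch, regime, t, directional_only))

  sol <- NULL
  for (tol in c(1e-8, 1e-10)) {
    sol <- deSolve::ode(y = p0, times = times, func = deriv, parms = NULL,
                        method = "lsoda", rtol = tol, atol = tol * 1e-2)
    y <- sol[, -1, drop = FALSE]
    over <- max(0, max(y) - 1, -min(y))
    if (!all(is.finite(y))) stop("integration produced non-finite frequencies")
    if (over <= 1e-12) break
  }
  if (over > 1e-12)
    stop("integrator overshot [0, 1] by ", signif(over, 3))
  y <- pmin(pmax(y, 0), 1)

  cum <- t(apply(cbind(times, y), 1, function(r) {
    cs <- compute_cumulants(arch, r[-1], optimum_at(regime, r[1]))
    c(cs$c1, cs$c2, cs$c3, cs$delta_c1)
  }))
  cum <- as.data.frame(cum)
  names(cum) <- c("c1", "c2", "c3", "delta_c1")

  out <- structure(list(times = times, freqs = y, cumulants = cum),
                   class = "det_trajectory")
  if (fit_rate)
    out$rate_estimate <- fit_decay_rate(times, cum$delta_c1,
                                        after = regime$shift_time)
  out
}

#' Fitted exponential decay rate of the trait-mean deviation
#'
#' Fits `log(|delta_c1(t) - delta_c1(Inf)|)` linearly in `t` over the window
#' in which the remaining deviation lies between fractions `hi` and `lo` of
#' its initial value, and returns minus the slope. The asymptote is taken as
#' the final recorded value, so the fit measures the approach rate toward
#' the (quasi-)equilibrium rather than toward the optimum itself.
#'
#' @param times generation vector.
#' @param delta_c1 deviation of the trait mean from the current optimum.
#' @param after only use times at or after this generation.
#' @param hi,lo fit window as fractions of the initial deviation.
#' @return Decay rate (1/generations).
#' @export
fit_decay_rate <- function(times, delta_c1, after = 0, hi = 0.9, lo = 0.1) {
  keep <- times >= after
  t <- times[keep]
  d <- delta_c1[keep]
  gap <- abs(d - d[length(d)])
  sel <- gap <= hi * gap[1] & gap >= lo * gap[1] & gap > 0
  if (sum(sel) < 3) stop("too few points in the decay window to fit a rate")
  -unname(coef(lm(log(gap[sel]) ~ t[sel]))[2])
}

#' Analytical short-term approach rate of the trait mean
#'
#' When most loci are minor (small effects), the trait mean approaches the
#' new optimum exponentially at rate `s * n * mean_effect^2` with `n` the
#' number of minor loci. When most effects are large, the rate is
#' proportional to `s * zf * mean_effect`; the proportionality constant is
#' not part of this model summary and is set to 1 here, so the large-effects
#' value should be read as a scale, not an absolute rate.
#'
#' @param arch a [trait_architecture()].
#' @param regime a [selection_regime()].
#' @param case `"small_effects"` or `"large_effects"`.
#' @return Rate (1/generations).
#' @export
short_term_rate <- function(arch, regime, case = c("small_effects", "large_effects")) {
  case <- match.arg(case)
  if (case == "small_effects") {
    n_minor <- sum(classify_loci(arch, regime$s) == "minor")
    regime$s * n_minor * arch$mean_effect^2
  } else {
    regime$s * regime$optimum_after * arch$mean_effect
  }
}

#' End of the short-term phase
#'
#' One time constant of the exponential approach, `1 / (s * c2(0))`
#' generations, matching the `1 - exp(-1)` factor in the frequency-shift
#' prediction of [predict_shifts()].
#'
#' @param s selection strength.
#' @param c2_0 genetic variance at the time of the optimum shift.
#' @return Time in generations.
#' @export
short_term_time <- function(s, c2_0) {
  if (c2_0 <= 0) stop("c2_0 must be > 0")
  1 / (s * c2_0)
}

#' Quasi-equilibrium deviation of the trait mean from the optimum
#'
#' Setting the fast dynamics of the trait mean to zero gives
#' \deqn{\tilde{\Delta c_1} \approx -\frac{(s/2)\,\tilde c_3 + 2\mu z_0}
#'   {s\,\tilde c_2 + 2\mu},}
#' showing that in equilibrium the mean sits close to, but not exactly at,
#' the optimum: the offset is set by the skewness of the trait distribution
#' and by mutation pressure.
#'
#' @param c2_eq,c3_eq quasi-equilibrium genetic variance and skewness.
#' @param mu per-locus mutation rate.
#' @param s selection strength.
#' @param z0 optimum.
#' @return The quasi-equilibrium deviation (trait units).
#' @export
quasi_equilibrium_deviation <- function(c2_eq, c3_eq, mu, s, z0) {
  den <- s * c2_eq + 2 * mu
  if (den <= 0) stop("s * c2_eq + 2 * mu must be > 0")
  -((s / 2) * c3_eq + 2 * mu * z0) / den
}

#' Predicted per-locus frequency shifts over the short-term phase
#'
#' For small effects and the trait mean relaxing exponentially toward the
#' new optimum, the shift of the "+"-allele frequency at locus `i` after one
#' time constant is approximately
#' \deqn{\delta p_i \approx -\gamma_i p_i(0) q_i(0) \Delta c_1(0)
#'   (1 - e^{-1}) / c_2(0).}
#' All shifts share the sign of `-delta_c1_0`: the allele frequencies move
#' coherently toward the new optimum, the hallmark of polygenic adaptation.
#'
#' @param arch a [trait_architecture()].
#' @param p0 frequencies at the time of the shift.
#' @param delta_c1_0 initial deviation of the trait mean from the new
#'   optimum.
#' @param c2_0 genetic variance at the time of the shift (> 0).
#' @return A list of class `shift_prediction` with `delta_p` and a logical
#'   `aligned` marking loci whose predicted shift points toward the new
#'   optimum.
#' @export
predict_shifts <- function(arch, p0, delta_c1_0, c2_0) {
  if (c2_0 <= 0) stop("c2_0 must be > 0 (no variance, no response)")
  dp <- -arch$effects * p0 * (1 - p0) * delta_c1_0 * (1 - exp(-1)) / c2_0
  structure(list(delta_p = dp, aligned = dp * sign(-delta_c1_0) > 0),
            class = "shift_prediction")
}

#' Label loci as sweep or shift candidates
#'
#' In an architecture dominated by major (large-effect) loci, a locus is
#' expected to sweep when its effect exceeds the mean effect. In an
#' architecture dominated by minor loci, a large frequency change requires
#' an effect exceeding the initial genetic variance, which is very unlikely
#' for exponentially distributed effects at many loci - polygenic
#' adaptation then proceeds by small coherent shifts instead.
#'
#' @param arch a [trait_architecture()].
#' @param regime a [selection_regime()].
#' @param p0 frequencies at the time of the shift (used for `c2(0)`).
#' @return Character vector per locus: `"sweep_expected"` or
#'   `"shift_expected"`.
#' @export
classify_sweep_candidates <- function(arch, regime, p0) {
  cls <- classify_loci(arch, regime$s)
  large_dominated <- mean(cls == "major") > 0.5
  if (large_dominated) {
    thr <- arch$mean_effect
  } else {
    thr <- compute_cumulants(arch, p0)$c2
  }
  ifelse(arch$effects > thr, "sweep_expected", "shift_expected")
}

#' Equilibrium frequencies of the deterministic model before a shift
#'
#' Minor loci equilibrate at frequency 1/2. Major loci sit in
#' mutation-selection balance near a frequency boundary; the balance point
#' is found numerically as the root of the per-locus dynamics (with the
#' trait mean held at the optimum, i.e. `delta_c1 = 0`) on `(0, 1/2)`.
#' The root near 0 is returned for every major locus; by the p <-> q
#' symmetry of the per-locus dynamics at `delta_c1 = 0`, the mirrored value
#' near 1 is an equally valid starting state.
#'
#' @param arch a [trait_architecture()].
#' @param regime a [selection_regime()].
#' @return Vector of equilibrium frequencies.
#' @export
equilibrium_frequencies <- function(arch, regime) {
  cls <- classify_loci(arch, regime$s)
  mu <- arch$mutation_rate
  s <- regime$s
  vapply(seq_len(arch$n_loci), function(i) {
    if (cls[i] == "minor") return(0.5)
    g <- arch$effects[i]
    if (mu == 0) return(0)
    # per-locus rhs with delta_c1 = 0 factorizes as
    # (q - p) * (mu - (s g^2 / 2) p q); the boundary root solves
    # p q = 2 mu / (s g^2), which exists for major loci by definition.
    uniroot(function(p) mu - (s * g^2 / 2) * p * (1 - p),
            interval = c(1e-300, 0.5 - 1e-12), tol = 1e-14)$root
  }, numeric(1))
}
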