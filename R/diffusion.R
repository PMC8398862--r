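#' Scaled parameters of the diffusion approximation
#'
#' `alpha = 2 N s` and `beta = 2 N mu` are the population-scaled selection
#' and mutation parameters; `gamma` is the locus effect size and
#' `delta_c1_tilde` the (constant) quasi-equilibrium deviation of the trait
#' mean from the optimum that the locus experiences as an external field.
#'
#' @param N diploid population size.
#' @param s selection strength.
#' @param mu per-locus mutation rate.
#' @param gamma locus effect size (trait units).
#' @param delta_c1_tilde quasi-equilibrium mean deviation (trait units).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(N, s, mu, gamma, delta_c1_tilde = 0) {
  alpha <- 2 * N * s
  beta <- 2 * N * mu
  if (alpha <= 0) stop("alpha = 2 N s must be > 0")
  if (beta < 0) stop("beta = 2 N mu must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 delta_c1_tilde = delta_c1_tilde, N = N, s = s, mu = mu),
            class = "diffusion_params")
}

# Unnormalized stationary density. The boundary exponent 2*beta - 1 is
# negative for beta < 1/2 (integrable singularity -> U shape).
.stat_kernel <- function(p, params) {
  with(params,
       p^(2 * beta - 1) * (1 - p)^(2 * beta - 1) *
         exp(-2 * alpha * gamma * delta_c1_tilde * p - alpha * gamma^2 * p * (1 - p)))
}

# Integrate h(p) * kernel(p) over (0,1) with the endpoint singularities
# removed by the substitution u = p^(2 beta) (left half) and its mirror
# (right half); tolerance 1e-8.
.stat_integral <- function(params, h = function(p) 1, rel.tol = 1e-8) {
  b2 <- 2 * params$beta
  smooth <- function(p) h(p) * .stat_kernel(p, params) / (p^(b2 - 1))
  left <- integrate(function(u) {
    p <- u^(1 / b2)
    smooth(p) / b2
  }, 0, 0.5^b2, rel.tol = rel.tol)$value
  smooth_r <- function(p) h(p) * .stat_kernel(p, params) / ((1 - p)^(b2 - 1))
  right <- integrate(function(u) {
    p <- 1 - u^(1 / b2)
    smooth_r(p) / b2
  }, 0, 0.5^b2, rel.tol = rel.tol)$value
  left + right
}

#' Stationary per-locus allele-frequency density
#'
#' Under the diffusion approximation with the trait-mean deviation held at
#' its quasi-equilibrium value, the stationary density of the "+"-allele
#' frequency at a locus with effect `gamma` is
#' \deqn{f(p) = C\, p^{2\beta - 1} q^{2\beta - 1}
#'   \exp(-2\alpha\gamma\tilde{\Delta c_1}\,p - \alpha\gamma^2 p q).}
#' The normalization `C` is computed by numerical quadrature (authoritative;
#' the closed-form beta-function approximation is available separately as
#' [normalization_approx()]). The density is U-shaped (mass piling up at
#' both frequency boundaries) when `2 beta < 1` and bell-shaped when
#' `beta > 0.5`.
#'
#' @param params a [diffusion_params()] with `beta > 0`.
#' @return An object of class `equilibrium_density`: fields `params`,
#'   `normalization` (the constant `C`), `shape` (`"U"` or `"bell"`), and
#'   `density`, a vectorized evaluator `f(p)` on (0, 1).
#' @export
stationary_density <- function(params) {
  if (params$beta <= 0) stop("beta must be > 0 for an integrable density")
  Z <- .stat_integral(params)
  if (!is.finite(Z) || Z <= 0) stop("quadrature failed to normalize the density")
  C <- 1 / Z
  f <- function(p) {
    if (any(p <= 0 | p >= 1)) stop("evaluate the density on (0, 1)")
    C * .stat_kernel(p, params)
  }
  structure(list(params = params, normalization = C,
                 shape = if (2 * params$beta < 1) "U" else "bell",
                 density = f),
            class = "equilibrium_density")
}

#' Moments of the stationary density
#'
#' Expectations of `p`, `p^2` and `p (1 - p)` under [stationary_density()],
#' computed by quadrature.
#'
#' @param params a [diffusion_params()].
#' @return Named list `mean`, `second`, `het` (`E[pq]`), `var`.
#' @export
stationary_moments <- function(params) {
  Z <- .stat_integral(params)
  m1 <- .stat_integral(params, function(p) p) / Z
  m2 <- .stat_integral(params, function(p) p^2) / Z
  list(mean = m1, second = m2, het = m1 - m2, var = m2 - m1^2)
}

#' Probability mass of the stationary density per histogram bin
#'
#' @param params a [diffusion_params()].
#' @param breaks bin boundaries covering \[0, 1\].
#' @return Vector of bin probabilities summing to 1.
#' @export
stationary_bin_probs <- function(params, breaks = seq(0, 1, by = 0.05)) {
  nb <- length(breaks) - 1
  b2 <- 2 * params$beta
  # endpoint bins via the singularity-removing substitution, interior bins
  # directly on the smooth kernel
  mass <- numeric(nb)
  mass[1] <- integrate(function(u) {
    p <- u^(1 / b2)
    .stat_kernel(p, params) / (p^(b2 - 1)) / b2
  }, 0, breaks[2]^b2, rel.tol = 1e-9)$value
  mass[nb] <- integrate(function(u) {
    p <- 1 - u^(1 / b2)
    .stat_kernel(p, params) / ((1 - p)^(b2 - 1)) / b2
  }, 0, (1 - breaks[nb])^b2, rel.tol = 1e-9)$value
  if (nb > 2)
    for (j in 2:(nb - 1))
      mass[j] <- integrate(.stat_kernel, breaks[j], breaks[j + 1],
                           params = params, rel.tol = 1e-9)$value
  mass / sum(mass)
}

#' Beta-function approximation of the normalization constant
#'
#' The closed-form approximation
#' `C^{-1} = B(2 beta, 2 beta) * [1 - alpha gamma delta_c1_tilde -
#' alpha gamma^2 beta / (4 beta + 1)]`, valid when the scaled selection
#' terms are small. When the bracket is not positive the approximation is
#' outside its domain and an error is raised; fall back to the quadrature
#' normalization of [stationary_density()] in that case.
#'
#' @param params a [diffusion_params()].
#' @return The approximate normalization constant `C`.
#' @export
normalization_approx <- function(params) {
  br <- with(params,
             1 - alpha * gamma * delta_c1_tilde - alpha * gamma^2 * beta / (4 * beta + 1))
  if (br <= 0)
    stop("approximation outside its validity range (bracket <= 0); ",
         "use the quadrature normalization instead")
  1 / (beta(2 * params$beta, 2 * params$beta) * br)
}

#' Equilibrium genetic variance under mutation-selection-drift balance
#'
#' For exponentially distributed effect sizes with mean `mean_effect`, the
#' stationary genetic variance is approximately
#' `(4 beta / (4 beta + 1)) * n * mean_effect^2` - reduced below the
#' deterministic value `n * mean_effect^2` because drift pushes allele
#' frequencies toward the boundaries where they contribute little variance.
#' The deterministic value is recovered as `beta -> Inf`. The formula uses
#' the neutral shape of the stationary density, so it slightly overestimates
#' the variance when scaled selection on individual loci
#' (`alpha * gamma^2`) is not negligible.
#'
#' @param n number of loci.
#' @param mean_effect mean effect size.
#' @param beta scaled mutation rate `2 N mu` (>= 0).
#' @return Genetic variance (trait units squared).
#' @export
equilibrium_variance <- function(n, mean_effect, beta) {
  if (beta < 0) stop("beta must be >= 0")
  if (is.infinite(beta)) return(n * mean_effect^2)
  (4 * beta / (4 * beta + 1)) * n * mean_effect^2
}

#' Moment dynamics of a locus during the adaptive phase
#'
#' Time derivatives of `E[p]`, `E[p^2]` and `E[pq]` for a locus of effect
#' `gamma` under directional selection of strength `s * gamma * delta_c1(t)`
#' and drift of strength `1/(2N)`:
#' \deqn{d E[p]/dt = -s\gamma\,E[pq]\,\Delta c_1(t)}
#' \deqn{d E[p^2]/dt = -2 s\gamma\,E[p^2 q]\,\Delta c_1(t) + E[pq]/(2N)}
#' \deqn{d E[pq]/dt = -s\gamma\,E[pq]\,\Delta c_1(t)
#'   + 2 s\gamma\,E[p^2 q]\,\Delta c_1(t) - E[pq]/(2N).}
#' The drift term `-E[pq]/(2N)` erodes the locus's variance contribution
#' regardless of selection. The third-order moment `E[p^2 q]` is not closed;
#' it is evaluated under a closure (see `closure`).
#'
#' @param moment_state named numeric vector `c(m1 = E[p], m2 = E[p^2])`.
#' @param gamma locus effect size.
#' @param s selection strength.
#' @param N diploid population size.
#' @param delta_c1_t current deviation of the trait mean from the optimum.
#' @param closure `"beta"` matches a beta distribution to the current mean
#'   and variance and evaluates `E[p^2 q]` under it (falling back to the
#'   mean-field product when the variance is at or beyond the two-point
#'   bound); `"mean_field"` uses `E[p^2 q] = E[p^2] * (1 - E[p])`.
#' @return Named vector of derivatives `c(m1, m2)` (note
#'   `d E[pq]/dt = d m1/dt - d m2/dt`).
#' @export
moment_dynamics <- function(moment_state, gamma, s, N, delta_c1_t,
                            closure = c("beta", "mean_field")) {
  closure <- match.arg(closure)
  m1 <- moment_state[["m1"]]
  m2 <- moment_state[["m2"]]
  if (m2 > m1 + 1e-12 || m2 < m1^2 - 1e-12)
    stop("inconsistent moments: need E[p]^2 <= E[p^2] <= E[p]")
  het <- m1 - m2
  m2q <- .closure_p2q(m1, m2, closure)
  dm1 <- -s * gamma * het * delta_c1_t
  dm2 <- -2 * s * gamma * m2q * delta_c1_t + het / (2 * N)
  c(m1 = dm1, m2 = dm2)
}

# E[p^2 (1-p)] under the chosen closure.
.closure_p2q <- function(m1, m2, closure) {
  if (closure == "mean_field") return(m2 * (1 - m1))
  v <- m2 - m1^2
  vmax <- m1 * (1 - m1)
  if (v <= 0) return(m2 * (1 - m1))
  if (v >= vmax * (1 - 1e-9)) {
    # two-point boundary limit: all mass at 0 and 1 -> E[p^2 q] = 0
    return(0)
  }
  ab <- m1 * (1 - m1) / v - 1
  a <- m1 * ab
  b <- (1 - m1) * ab
  m3 <- a * (a + 1) * (a + 2) / ((ab) * (ab + 1) * (ab + 2))
  m2b <- a * (a + 1) / (ab * (ab + 1))
  m2b - m3
}

#' Integrate the moment dynamics
#'
#' @inheritParams moment_dynamics
#' @param m1_0,m2_0 initial `E[p]`, `E[p^2]`.
#' @param delta_c1_fun function of time giving `delta_c1(t)`; use
#'   `function(t) 0` for the no-selection (pure drift) case.
#' @param t_max,dt integration horizon and output interval (generations).
#' @return Data frame with `time`, `m1`, `m2`, `het`.
#' @export
integrate_moments <- function(gamma, s, N, m1_0, m2_0, delta_c1_fun,
                              t_max, dt = 1, closure = "beta") {
  deriv <- function(t, y, parms) {
    d <- moment_dynamics(c(m1 = y[1], m2 = y[2]), gamma, s, N,
                         delta_c1_fun(t), closure = closure)
    list(unname(d))
  }
  sol <- deSolve::ode(y = c(m1_0, m2_0), times = seq(0, t_max, by = dt),
                      func = deriv, parms = NULL, rtol = 1e-8, atol = 1e-10)
  data.frame(time = sol[, 1], m1 = sol[, 2], m2 = sol[, 3],
             het = sol[, 2] - sol[, 3])
}
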