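---
title: "Modelling rapid polygenic adaptation under stabilizing selection, mutation and drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rapid polygenic adaptation under stabilizing selection, mutation and drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`polytrait` models a perfectly heritable quantitative trait controlled
additively by $n$ unlinked diallelic loci in a randomly mating diploid
population. The "+" allele at locus $i$ contributes $+\gamma_i/2$ to the
phenotype and the "−" allele $-\gamma_i/2$, so with "+"-allele frequencies
$p_i$ (and $q_i = 1 - p_i$) the trait distribution has cumulants

$$c_1 = \sum_i \gamma_i (p_i - q_i), \qquad
  c_2 = 2 \sum_i \gamma_i^2 p_i q_i, \qquad
  c_3 = 2 \sum_i \gamma_i^3 p_i q_i (q_i - p_i).$$

Fitness is Gaussian about an optimum $z_{\mathrm{opt}}$,
$w(z) = \exp\{-(s/2)(z - z_{\mathrm{opt}})^2\}$, with $1/s$ much larger
than the phenotypic variance. Selection and symmetric mutation ($\mu$ per
locus per generation) give the coupled deterministic dynamics

$$\frac{dp_i}{dt} = -s\gamma_i p_i q_i \,\Delta c_1
  \;-\; \frac{s\gamma_i^2}{2} p_i q_i (q_i - p_i) \;+\; \mu (q_i - p_i),$$

where $\Delta c_1 = c_1 - z_{\mathrm{opt}}$. The first term is directional
selection toward the optimum and couples all loci through the trait mean;
the second is stabilizing selection; the third is mutation. Effect sizes
are drawn i.i.d. exponential with mean $\bar\gamma$
(`sample_architecture()`), the standard assumption for quantitative-trait
loci in this model family.

Loci split into *minor* and *major* at the stability threshold
$\hat\gamma = 2\sqrt{2\mu/s}$ (`effect_threshold()`): minor loci
equilibrate near frequency $1/2$ and carry most of the standing variance,
while major loci sit in mutation–selection balance near a frequency
boundary ($p q = 2\mu/s\gamma^2$, solved numerically in
`equilibrium_frequencies()`).

Two printed forms of these expressions in the source literature are
typographically garbled; we implement the standard readings
$\hat\gamma = 2\sqrt{2\mu/s}$ (the stability condition for internal
equilibria, which requires $\gamma^2 > 8\mu/s$) and
$w(z) = \exp\{-(s/2)(z-z_0)^2\}$.

## Short-term adaptation after an optimum shift

When the optimum jumps from $z_0$ to $z_f$ (with
$0 < z_0 < z_f < n\bar\gamma$ so the mean can settle near the new
optimum), the early dynamics are dominated by the directional term
(`integrate_trajectory(..., directional_only = TRUE)`): the trait mean
approaches the optimum approximately exponentially. For architectures of
many small effects the rate is $s\,n\,\bar\gamma^2$ — i.e. $s\,c_2(0)$ with
the equilibrium variance $c_2(0) \approx n \bar\gamma^2$ — so adaptation is
fast when many loci contribute. For large effects the rate instead scales
as $s z_f \bar\gamma$; `short_term_rate()` exposes the large-effects value
as a scale with proportionality constant 1, since the constant is not part
of this model summary.

We define the *end of the short-term phase* operationally as one time
constant, $t^\ast = 1/(s\,c_2(0))$ (`short_term_time()`); this matches the
$1 - e^{-1}$ factor in the per-locus shift prediction

$$\delta p_i \approx -\gamma_i\, p_i(0) q_i(0)\, \Delta c_1(0)\,
  \frac{1 - e^{-1}}{c_2(0)}$$

implemented in `predict_shifts()`. All predicted shifts share the sign of
$-\Delta c_1(0)$: small coherent frequency shifts at many loci are the
signature of polygenic adaptation, in contrast to selective sweeps at
large-effect loci (`classify_sweep_candidates()`: in a major-dominated
architecture, loci with $\gamma_i > \bar\gamma$ are sweep candidates; in a
minor-dominated one an effect exceeding $c_2(0)$ would be required, which
is exponentially unlikely).

The deterministic integrator is adaptive (lsoda, relative tolerance
$10^{-8}$); trajectories are cross-validated in the test suite against a
fixed-step Euler oracle at $dt = 10^{-3}$, and overshoots of $[0,1]$
beyond $10^{-12}$ trigger a tighter-tolerance retry rather than clipping.

## Finite populations

`wf_simulate()` iterates, per generation: the deterministic expected
update (with $\Delta c_1$ evaluated from the live frequency vector), then
binomial resampling $p_i' \sim \mathrm{Binomial}(2N, p_i^\ast)/2N$
independently per locus. Because the loci are unlinked and the trait is
additive, these per-locus frequency dynamics are exact for the model at
linkage equilibrium; we deliberately do not simulate individuals, which
would be orders of magnitude slower and add nothing for unlinked loci.
This is also the fidelity boundary of the package: linked neutral
variation, hitchhiking footprints, dominance, epistasis and pleiotropy are
out of scope. The per-generation loop is compiled (Rcpp) and draws from
R's RNG, so runs are bit-reproducible from `set.seed()`; experiment
drivers derive one sub-stream seed per replicate from the master seed by a
fixed documented rule. Applying the deterministic update before sampling
(rather than after) differs only at $O(1/N)$.

In the stochastic equilibrium the trait mean fluctuates around a value
close to, but not at, the optimum. Setting the fast dynamics of the mean
to zero gives the quasi-equilibrium deviation

$$\tilde{\Delta c_1} \approx -\frac{(s/2)\,\tilde c_3 + 2\mu z_0}
  {s\,\tilde c_2 + 2\mu}$$

(`quasi_equilibrium_deviation()`), set by the skew of the trait
distribution and mutation pressure. At the standard parameter set used
throughout ($s = 0.1$, $N = 2\times10^4$, $n = 200$, $\mu = 10^{-5}$,
$\bar\gamma = 0.01$, $z_0 = 0.2$; values from the human polygenic
adaptation literature) the measured value is about $-0.002$ to $-0.003$.
The instantaneous deviation fluctuates like an Ornstein–Uhlenbeck process
with stationary standard deviation $\approx 1/\sqrt{2Ns} = 0.016$ and
correlation time $\approx 1/(s c_2) \sim 10^3$ generations — an order of
magnitude larger than its mean. Estimating the mean deviation therefore
requires time-averaging over $\sim 10^6$ generations; the package's
equilibrium drivers use windows of that order. Statistics built on the
deviation should be interpreted with this fluctuation structure in mind:
averages of $|\Delta c_1|$ measure the fluctuation scale, not the mean,
whenever the sd exceeds the mean (it does at all parameter sets used
here).

## Diffusion theory

With $\alpha = 2Ns$ and $\beta = 2N\mu$, the stationary density of a
locus experiencing a constant mean deviation $\tilde{\Delta c_1}$ is

$$f(p) \propto (pq)^{2\beta - 1}
  \exp\{-2\alpha\gamma\tilde{\Delta c_1}\,p - \alpha\gamma^2 pq\},$$

U-shaped when $2\beta < 1$ and bell-shaped when $\beta > 0.5$
(`stationary_density()`). Normalization is by quadrature with the
endpoint singularities removed by the substitution $u = p^{2\beta}$
(tolerance $10^{-8}$); the closed-form beta-function approximation
$C^{-1} \approx B(2\beta,2\beta)\,[1 - \alpha\gamma\tilde{\Delta c_1} -
\alpha\gamma^2\beta/(4\beta+1)]$ is exposed as `normalization_approx()`
with its validity bracket checked, but quadrature is authoritative — the
closed form is itself an expansion for small scaled-selection terms.

Under the neutral shape of this density the standing genetic variance for
exponential effects is approximately
$\frac{4\beta}{4\beta+1} n \bar\gamma^2$ (`equilibrium_variance()`),
reduced below the deterministic $n\bar\gamma^2$ because drift piles
frequencies up near the boundaries. Two systematic effects bracket the
truth at the standard parameters: the formula neglects the
$\alpha\gamma^2$ selection factor (which pushes variance further down —
simulations give a time-averaged $c_2$ about 15% below the formula's
0.0123), while the full constant-field density over-corrects (predicting
about 0.0089), because in reality the trait-mean deviation fluctuates and
acts as a self-consistent restoring field that keeps frequencies more
intermediate. The simulated value sits between the two approximations;
the package reports measured values and exposes both theory levels.

For the adaptive phase, the moment dynamics of a locus under directional
selection and drift are

$$\tfrac{d}{dt}E[p] = -s\gamma\,E[pq]\,\Delta c_1(t), \qquad
  \tfrac{d}{dt}E[pq] = -s\gamma\,E[pq]\,\Delta c_1(t)
  + 2s\gamma\,E[p^2q]\,\Delta c_1(t) - \frac{E[pq]}{2N},$$

whose $-E[pq]/2N$ term shows drift eroding each locus's variance
contribution — the reason adaptation stalls in small populations. The
third moment $E[p^2 q]$ is not closed; `moment_dynamics()` evaluates it
under a beta-distribution ansatz matched to the current mean and variance
(falling back to the mean-field product at the two-point boundary limit),
a closure validated against Wright–Fisher ensembles in the test suite.
The closure is a configurable argument, not a hidden constant.

## Experiment drivers and design choices

**Equilibrium fit (`experiment_figure1()`).** Burn-in at the standard
parameters, then pool sampled frequencies and compare with the stationary
density; the trait-mean deviation entering the density is the measured
time-average by default (an Eq.-9-style fixed point from measured
$\tilde c_2, \tilde c_3$ is the alternative mode). A focal locus with
$\gamma = 0.0107$ is pinned into the sampled architecture for
like-for-like single-locus comparisons. Two pooling modes exist because
of a hard statistical constraint: a single locus decorrelates only over
$\sim 2N$ generations (measured autocorrelation e-folding
$\approx 4\times10^4$ generations here), so the pooled focal-locus sample
at desk scale has an effective size of tens and its 20-bin
total-variation distance from theory is dominated by Monte-Carlo noise
(we measure TV $\approx 0.16$–$0.44$ at 3–6 replicates even though the
theory is accurate). Pooling *all* loci against the corresponding mixture
of per-locus densities multiplies the effective sample by roughly the
locus number — the loci interact only through the weak mean-field
coupling — and yields TV $\approx 0.006$–$0.012$ at the same compute.
The all-locus mixture comparison is therefore the default fit statistic;
`pool = "focal"` remains available for long dedicated runs. Histograms
use 20 equal bins (configurable).

**Bottleneck (`experiment_bottleneck()`).** Default protocol mimics a
well-studied demographic history: $N = 2\times10^4$ reduced to 3000 for
5000 generations. The baseline is the time-average over the last 2000
generations of burn-in pooled across replicates ($\geq 100$ by default),
the end state the pooled average over the final 1000 bottleneck
generations. Burn-in defaults to $8N$ generations: frequencies relax to
stationarity over order $2N$, and a percent change measured against a
still-relaxing baseline (e.g. after only $3N$) conflates the bottleneck
response with the remaining transient — `burn_in()`'s first-half /
second-half variance diagnostic makes this visible. The reported
deviation change is that of the pooled $|\Delta c_1|$. Expected
behaviour at the default parameters: the genetic variance falls by
roughly 40% (monotonically, tracking the $-E[pq]/2N$ drift term of the
moment dynamics), while the pooled absolute deviation rises by roughly
$\sqrt{N_{\mathrm{base}}/N_{\mathrm{bneck}}}$ (measured $+150$ to
$+180\%$ at the defaults, varying with architecture draw and replicate
count), because it is dominated by the drift fluctuations of the trait
mean.
Three deviation statistics are returned because they measure different
things and differ by an order of magnitude in measurability: the pooled
absolute deviation (robust, fluctuation-dominated), the signed ensemble
mean (the quasi-equilibrium deviation itself, but with standard error
far above its value at feasible replicate counts), and the
quasi-equilibrium value implied by the pooled cumulants through the
balance equation (precise, but a near-cancellation of the skew and
mutation terms, so its *relative* change across conditions is
ill-conditioned and architecture-sensitive).

**Regime panel (`experiment_regimes()`).** Deterministic shift dynamics
across minor-only, mixed and major-dominated architectures: fitted
approach rates and counts of loci crossing $p > 0.95$ within $t^\ast$
(sweeps). Minor-only panels produce no sweeps; major-dominated panels
produce at least one.

## Numerical and statistical choices

* Integrators: lsoda with rtol $10^{-8}$ (trajectories), rtol $10^{-8}$ /
  atol $10^{-10}$ (moments); quadrature tolerance $10^{-8}$ with
  singularity-removing substitutions.
* Binomial sampling is exact (R's `rbinom`), never a normal
  approximation, so boundary behaviour (fixation/loss and mutation-driven
  re-entry) is faithful.
* Problem sizes in the test suite: equilibrium averages use three
  $200$-locus replicates of $3N$ burn-in plus $3\times10^5$ sampled
  generations (pooled SE on the mean deviation $\approx 7\times10^{-4}$);
  the bottleneck check uses 60 replicates; the density fit uses 4
  replicates of $2\times10^5$ sampled generations with all-locus pooling;
  distribution-level deterministic statements (equilibrium variance,
  approach rates) average over 8–100 architecture draws because the
  realized $\sum_i \gamma_i^2$ of a single 200-locus exponential draw
  fluctuates by $\approx 16\%$ around $2n\bar\gamma^2$.
* Ties/degenerate inputs: $\mu = 0$ makes every locus major and the
  boundary equilibria absorbing; `predict_shifts()` and
  `short_term_time()` refuse $c_2(0) = 0$ (no variance, no response);
  the minor/major threshold at $\gamma = \hat\gamma$ assigns the locus to
  the major class.

## What the synthetic data do and do not show

All validation inputs are generated by the package itself (exponential
architectures, Wright–Fisher trajectories); there is no external data.
Agreement of simulation with the diffusion predictions shows internal
consistency of the model chain — it does not validate the biological
assumptions (strict additivity, unlinked loci, constant Gaussian
stabilizing selection, symmetric single-rate mutation, exponential
effects). Real traits involve linkage, pleiotropy, dominance and
environmental variance, all outside this package's fidelity boundary.

## Known limitations

* The large-effects approach rate is exposed only up to a proportionality
  constant.
* Slow quasi-fixations (large-effect trajectories that creep to fixation
  over $\sim 10^3 \times$ the short-term phase without sweep signatures)
  are observable in trajectories but not flagged by a dedicated
  operation, as no quantitative criterion is available.
* The stationary density assumes a constant mean-deviation field; its
  fluctuations make the theory slightly boundary-heavy relative to
  simulation (see the variance discussion above).
* Demography schedules change $N$ stepwise per generation; overlapping
  generations and continuous growth are not modelled.
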