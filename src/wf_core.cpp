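#include <Rcpp.h>
using namespace Rcpp;

// Forward Wright-Fisher engine for n unlinked diallelic loci controlling an
// additive trait under Gaussian stabilizing selection and symmetric mutation.
//
// Per generation, in this order:
//   1. trait mean c1 and its deviation from the current optimum are computed
//      from the full current frequency vector (the loci are coupled only
//      through this term);
//   2. the deterministic expectation of the next frequency is formed per
//      locus:  p* = p + [ -s*g*p*q*dc1 - (s*g^2/2)*p*q*(q-p) + mu*(q-p) ]
//      and clipped to [0,1];
//   3. the realized next frequency is Binomial(2N, p*)/(2N), drawn
//      independently per locus (linkage equilibrium is exact for unlinked
//      loci under this model).
//
// Uses R's RNG, so results are reproducible via set.seed() from R.
//
// opt_by_gen and N_by_gen have one entry per simulated generation, which is
// how optimum shifts and demography (bottlenecks) enter.
//
// Recording: states after generation g (1-based) are stored whenever
// g %% thin == 0; thin = 0 disables that stream. Cumulants (c1, c2, c3) and
// the frequencies of `record_loci` (1-based indices) are recorded on
// independent thinning intervals so long runs stay memory-bounded.

// [[Rcpp::export]]
List wf_run_cpp(NumericVector p0, NumericVector effects, double s, double mu,
                NumericVector opt_by_gen, IntegerVector N_by_gen,
                int thin_cum, int thin_freq, IntegerVector record_loci) {
  const int n = p0.size();
  const int gens = opt_by_gen.size();
  if (N_by_gen.size() != gens)
    stop("opt_by_gen and N_by_gen must have one entry per generation");
  if (effects.size() != n) stop("effects and p0 lengths differ");

  std::vector<double> p(p0.begin(), p0.end());
  const std::vector<double> g(effects.begin(), effects.end());

  const int n_cum = (thin_cum > 0) ? gens / thin_cum : 0;
  const int n_frq = (thin_freq > 0) ? gens / thin_freq : 0;
  const int n_rec = record_loci.size();

  IntegerVector t_cum(n_cum), t_frq(n_frq);
  NumericVector c1_out(n_cum), c2_out(n_cum), c3_out(n_cum);
  NumericMatrix freq_out(n_frq, n_rec);

  int i_cum = 0, i_frq = 0;
  for (int t = 0; t < gens; ++t) {
    // trait mean from the full current frequency vector
    double c1 = 0.0;
    for (int i = 0; i < n; ++i) c1 += g[i] * (2.0 * p[i] - 1.0);
    const double dc1 = c1 - opt_by_gen[t];
    const double two_n = 2.0 * static_cast<double>(N_by_gen[t]);

    for (int i = 0; i < n; ++i) {
      const double pi = p[i], qi = 1.0 - pi;
      const double pq = pi * qi;
      double ep = pi - s * g[i] * pq * dc1
                     - 0.5 * s * g[i] * g[i] * pq * (qi - pi)
                     + mu * (qi - pi);
      if (ep < 0.0) ep = 0.0; else if (ep > 1.0) ep = 1.0;
      p[i] = R::rbinom(two_n, ep) / two_n;
    }

    const int gen1 = t + 1;
    if (thin_cum > 0 && gen1 % thin_cum == 0 && i_cum < n_cum) {
      double c2 = 0.0, c3 = 0.0, c1n = 0.0;
      for (int i = 0; i < n; ++i) {
        const double pq = p[i] * (1.0 - p[i]);
        c1n += g[i] * (2.0 * p[i] - 1.0);
        c2 += g[i] * g[i] * pq;
        c3 += g[i] * g[i] * g[i] * pq * (1.0 - 2.0 * p[i]);
      }
      t_cum[i_cum] = gen1;
      c1_out[i_cum] = c1n;
      c2_out[i_cum] = 2.0 * c2;
      c3_out[i_cum] = 2.0 * c3;
      ++i_cum;
    }
    if (thin_freq > 0 && gen1 % thin_freq == 0 && i_frq < n_frq) {
      t_frq[i_frq] = gen1;
      for (int k = 0; k < n_rec; ++k) freq_out(i_frq, k) = p[record_loci[k] - 1];
      ++i_frq;
    }
    if (t % 8192 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["p_final"] = NumericVector(p.begin(), p.end()),
                      _["t_cum"] = t_cum, _["c1"] = c1_out, _["c2"] = c2_out,
                      _["c3"] = c3_out, _["t_freq"] = t_frq,
                      _["freq"] = freq_out);
}
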