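#include <Rcpp.h>
using namespace Rcpp;

// Exact marginal log-likelihood of the single-season hierarchy with the
// latent count layers summed out.  Given N_super, the per-visit detected
// counts are iid Binomial(N_super, q) with q = p_p * phi * p_d (presence is
// re-drawn each visit), so the point-level likelihood is a 1-D sum over
// N_super against its Poisson prior.  Distance-class and time-interval
// records contribute conditional multinomial cell terms.
//
// y holds the UNIQUE count rows (points x visits) with multiplicities w_y;
// the sum over points weights each unique row.  lgam[i] must hold
// lgamma(i + 1) for i = 0..(table size - 1); the R caller sizes it to
// cover the Poisson truncation point.

static inline double lg(const NumericVector &lgam, int i) {
  if (i < lgam.size()) return lgam[i];
  return R::lgammafn(i + 1.0);
}

// [[Rcpp::export]]
double staticLogLik(const IntegerMatrix &y, const IntegerVector &w_y,
                    const IntegerVector &ndist, const IntegerVector &ntime,
                    const NumericVector &mid, const NumericVector &w,
                    double B, double lambda, double p_p, double p_a,
                    double sigma, const NumericVector &lgam) {
  const int U = y.nrow(), T = y.ncol();
  const int nb = mid.size(), J = ntime.size();
  if (lambda <= 0.0 || sigma <= 0.0 || p_p <= 0.0 || p_p >= 1.0 ||
      p_a <= 0.0 || p_a >= 1.0)
    return R_NegInf;

  // distance cells (rectangular rule at bin midpoints)
  std::vector<double> pi_d(nb);
  double p_d = 0.0;
  for (int b = 0; b < nb; b++) {
    pi_d[b] = std::exp(-mid[b] * mid[b] / (2.0 * sigma * sigma)) *
              2.0 * mid[b] * w[b] / (B * B);
    p_d += pi_d[b];
  }
  // geometric removal cells
  std::vector<double> pi_a(J);
  double phi = 0.0, om = 1.0;
  for (int j = 0; j < J; j++) {
    pi_a[j] = p_a * om;
    phi += pi_a[j];
    om *= (1.0 - p_a);
  }

  double ll = 0.0;
  for (int b = 0; b < nb; b++)
    if (ndist[b] > 0) ll += ndist[b] * std::log(pi_d[b] / p_d);
  for (int j = 0; j < J; j++)
    if (ntime[j] > 0) ll += ntime[j] * std::log(pi_a[j] / phi);

  const double q = p_p * phi * p_d;
  const double logq = std::log(q), log1mq = std::log1p(-q);
  const double loglam = std::log(lambda);
  // truncation: generous upper tail of Poisson(lambda), at least max count
  int Nmax = (int)std::ceil(lambda + 10.0 * std::sqrt(lambda) + 25.0);
  int ymaxAll = 0;
  for (int u = 0; u < U; u++)
    for (int t = 0; t < T; t++) ymaxAll = std::max(ymaxAll, y(u, t));
  const int hi = std::max(Nmax, ymaxAll);

  // terms that depend on N only:
  //   log dpois(N | lambda) + T * lchoose-numerator + T * N * log(1 - q)
  std::vector<double> aN(hi + 1), buf(hi + 1);
  for (int N = 0; N <= hi; N++)
    aN[N] = N * loglam - lambda + (T - 1.0) * lg(lgam, N) +
            (double)T * N * log1mq;

  const double dq = logq - log1mq;
  for (int u = 0; u < U; u++) {
    int ymax = 0, sy = 0;
    double lgy = 0.0;
    for (int t = 0; t < T; t++) {
      const int yt = y(u, t);
      ymax = std::max(ymax, yt);
      sy += yt;
      lgy += lg(lgam, yt);
    }
    const double cst = sy * dq - lgy;
    double m = R_NegInf;
    for (int N = ymax; N <= hi; N++) {
      double s = 0.0;
      for (int t = 0; t < T; t++) s += lg(lgam, N - y(u, t));
      const double lp = aN[N] - s + cst;
      buf[N] = lp;
      if (lp > m) m = lp;
    }
    double sum = 0.0;
    for (int N = ymax; N <= hi; N++) sum += std::exp(buf[N] - m);
    ll += w_y[u] * (m + std::log(sum));
  }
  return ll;
}
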