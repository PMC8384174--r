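#include <Rcpp.h>
using namespace Rcpp;

// dbinom(s; m, om) for s = 0..K (zero beyond m), filled by a
// multiplicative recurrence anchored at the mode so no intermediate
// underflows. Handles the om = 0 / 1 edges exactly.
static void binom_row(int m, double om, std::vector<double> &out, int K) {
  std::fill(out.begin(), out.end(), 0.0);
  if (m == 0) { out[0] = 1.0; return; }
  if (om <= 0.0) { out[0] = 1.0; return; }
  if (om >= 1.0) { if (m <= K) out[m] = 1.0; return; }
  int mode = (int)std::floor((m + 1) * om);
  if (mode > m) mode = m;
  int top = std::min(m, K);
  if (mode > top) mode = top;
  out[mode] = std::exp(R::dbinom(mode, m, om, 1));
  double ratio = om / (1.0 - om);
  for (int s = mode; s < top; s++)
    out[s + 1] = out[s] * ratio * (double)(m - s) / (double)(s + 1);
  for (int s = mode; s > 0; s--)
    out[s - 1] = out[s] / ratio * (double)s / (double)(m - s + 1);
}

// Poisson(gamma) pmf for 0..K; returns the largest index holding
// all but ~1e-15 of the mass, so convolutions can stop early.
static int pois_vec(double gamma, std::vector<double> &out, int K) {
  std::fill(out.begin(), out.end(), 0.0);
  if (gamma <= 0.0) { out[0] = 1.0; return 0; }
  out[0] = std::exp(-gamma);
  double cum = out[0];
  int qmax = 0;
  for (int j = 1; j <= K; j++) {
    out[j] = out[j - 1] * gamma / j;
    cum += out[j];
    qmax = j;
    if (cum > 1.0 - 1e-15 && j > gamma) break;
  }
  return qmax;
}

// Binomial detection weights dbinom(y; n, p) for n = 0..K via upward
// recurrence from n = y.
static void emission_row(int y, double p, std::vector<double> &out,
                         int K) {
  std::fill(out.begin(), out.end(), 0.0);
  if (y > K) return;
  if (p <= 0.0) { if (y == 0) std::fill(out.begin(), out.end(), 1.0);
                  return; }
  if (p >= 1.0) { out[y] = 1.0; return; }
  out[y] = std::pow(p, y);
  for (int n = y; n < K; n++)
    out[n + 1] = out[n] * (1.0 - p) * (double)(n + 1) /
      (double)(n + 1 - y);
}

static int fill_transition(NumericMatrix &tr, int K, double gamma,
                           double omega) {
  std::vector<double> pois(K + 1), brow(K + 1);
  int qmax = pois_vec(gamma, pois, K);
  for (int m = 0; m <= K; m++) {
    binom_row(m, omega, brow, K);
    for (int s = 0; s <= std::min(m, K); s++) {
      double b = brow[s];
      if (b == 0.0) continue;
      int ntop = std::min(K, s + qmax);
      for (int n = s; n <= ntop; n++) tr(m, n) += b * pois[n - s];
    }
  }
  return qmax;
}

// highest state index whose mass is within a factor 1e-25 of the peak;
// states beyond it are numerically irrelevant to the forward sums
static int support_top(const std::vector<double> &phi, int K) {
  double mx = 0.0;
  for (int n = 0; n <= K; n++) if (phi[n] > mx) mx = phi[n];
  double thr = mx * 1e-25;
  int top = 0;
  for (int n = K; n >= 0; n--) if (phi[n] > thr) { top = n; break; }
  return top;
}

// Transition kernel of the open N-mixture dynamics on {0..K}:
// P(N_t = n | N_{t-1} = m) = sum_s Binom(s; m, omega) * Pois(n - s; gamma).
// Rows are the previous state m, columns the next state n. Rows sum to
// 1 minus the mass truncated above K.
// [[Rcpp::export]]
NumericMatrix cpp_dm_transition(int K, double gamma, double omega) {
  NumericMatrix tr(K + 1, K + 1);
  fill_transition(tr, K, gamma, omega);
  return tr;
}

// Unnormalized initial pmf over {0..K}: Poisson(lambda) or negative
// binomial with size alpha and mean lambda. Truncation mass is left off,
// never folded back in.
static void initial_pmf_fill(std::vector<double> &phi, double lambda,
                             int K, bool nb, double alpha) {
  if (lambda <= 0.0) {
    std::fill(phi.begin(), phi.end(), 0.0);
    phi[0] = 1.0;
    return;
  }
  if (nb) {
    for (int n = 0; n <= K; n++)
      phi[n] = R::dnbinom_mu(n, alpha, lambda, 0);
  } else {
    phi[0] = std::exp(-lambda);
    if (phi[0] == 0.0) {  // very large lambda: anchor at the mode
      for (int n = 0; n <= K; n++) phi[n] = R::dpois(n, lambda, 0);
    } else {
      for (int n = 1; n <= K; n++) phi[n] = phi[n - 1] * lambda / n;
    }
  }
}

// Per-site log-likelihood of the open N-mixture model by forward
// recursion over the latent abundance, with running rescaling so small
// detection probabilities do not underflow. Unsurveyed occasions (mask
// false) contribute no detection term but the dynamics still advance.
// [[Rcpp::export]]
NumericVector cpp_dm_site_loglik(IntegerMatrix y, LogicalMatrix mask,
                                 NumericVector lambda, NumericMatrix p,
                                 double gamma, double omega, int K,
                                 bool nb, double alpha) {
  int M = y.nrow(), T = y.ncol();
  NumericVector ll(M);
  std::vector<double> pois(K + 1);
  int qmax = (T > 1) ? pois_vec(gamma, pois, K) : 0;

  // global working bound: states above it carry a relative initial mass
  // below ~1e-25 at every site and can never be reached by the observed
  // counts plus recruit spread, so capping there is numerically exact
  std::vector<double> phi(K + 1), nxt(K + 1), emis(K + 1);
  int G = 0;
  for (int i = 0; i < M; i++) {
    initial_pmf_fill(phi, lambda[i], K, nb, alpha);
    int ti = support_top(phi, K);
    for (int t = 0; t < T; t++) if (mask(i, t) && y(i, t) > ti)
      ti = y(i, t);
    if (ti > G) G = ti;
  }
  G = std::min(K, G + (T - 1) * qmax);

  NumericMatrix tr(G + 1, G + 1);
  if (T > 1) {
    std::vector<double> brow(G + 1);
    for (int m = 0; m <= G; m++) {
      binom_row(m, omega, brow, G);
      for (int s = 0; s <= m; s++) {
        double b = brow[s];
        if (b == 0.0) continue;
        int ntop = std::min(G, s + qmax);
        for (int n = s; n <= ntop; n++) tr(m, n) += b * pois[n - s];
      }
    }
  }

  for (int i = 0; i < M; i++) {
    double logscale = 0.0;
    initial_pmf_fill(phi, lambda[i], K, nb, alpha);
    for (int t = 0; t < T; t++) {
      if (t > 0) {
        int mtop = support_top(phi, G);
        int ntop = std::min(G, mtop + qmax);
        for (int n = 0; n <= ntop; n++) nxt[n] = 0.0;
        for (int m = 0; m <= mtop; m++) {
          double pm = phi[m];
          if (pm == 0.0) continue;
          for (int n = 0; n <= ntop; n++) nxt[n] += pm * tr(m, n);
        }
        for (int n = ntop + 1; n <= G; n++) nxt[n] = 0.0;
        std::swap(phi, nxt);
      }
      if (mask(i, t)) {
        emission_row(y(i, t), p(i, t), emis, G);
        for (int n = 0; n <= G; n++) phi[n] *= emis[n];
      }
      double tot = 0.0;
      for (int n = 0; n <= G; n++) tot += phi[n];
      if (tot <= 0.0 || !R_finite(tot)) { logscale = R_NegInf; break; }
      logscale += std::log(tot);
      for (int n = 0; n <= G; n++) phi[n] /= tot;
    }
    ll[i] = logscale;
  }
  return ll;
}

// Forward (alpha) and backward (beta) matrices over {0..K} for one site,
// for the empirical-Bayes posterior of the latent abundance at each
// occasion. alpha columns are the filtered distributions (rescaled to
// sum to one); beta columns carry the matching likelihood complements,
// so alpha * beta renormalized is the smoothing posterior.
// [[Rcpp::export]]
List cpp_dm_forward_backward(IntegerVector y, LogicalVector mask,
                             double lambda, NumericVector p,
                             double gamma, double omega, int K,
                             bool nb, double alpha) {
  int T = y.size();
  NumericMatrix tr(K + 1, K + 1);
  if (T > 1) fill_transition(tr, K, gamma, omega);
  NumericMatrix A(K + 1, T), B(K + 1, T);
  std::vector<double> phi(K + 1), nxt(K + 1), emis(K + 1);
  initial_pmf_fill(phi, lambda, K, nb, alpha);
  for (int t = 0; t < T; t++) {
    if (t > 0) {
      for (int n = 0; n <= K; n++) nxt[n] = 0.0;
      for (int m = 0; m <= K; m++) {
        double pm = phi[m];
        if (pm == 0.0) continue;
        for (int n = 0; n <= K; n++) nxt[n] += pm * tr(m, n);
      }
      std::swap(phi, nxt);
    }
    if (mask[t]) {
      emission_row(y[t], p[t], emis, K);
      for (int n = 0; n <= K; n++) phi[n] *= emis[n];
    }
    double tot = 0.0;
    for (int n = 0; n <= K; n++) tot += phi[n];
    if (tot > 0) for (int n = 0; n <= K; n++) phi[n] /= tot;
    for (int n = 0; n <= K; n++) A(n, t) = phi[n];
  }
  for (int n = 0; n <= K; n++) B(n, T - 1) = 1.0;
  for (int t = T - 2; t >= 0; t--) {
    if (mask[t + 1]) emission_row(y[t + 1], p[t + 1], emis, K);
    else std::fill(emis.begin(), emis.end(), 1.0);
    for (int m = 0; m <= K; m++) {
      double acc = 0.0;
      for (int n = 0; n <= K; n++) acc += tr(m, n) * emis[n] * B(n, t + 1);
      B(m, t) = acc;
    }
    double mx = 0.0;
    for (int m = 0; m <= K; m++) if (B(m, t) > mx) mx = B(m, t);
    if (mx > 0) for (int m = 0; m <= K; m++) B(m, t) /= mx;
  }
  return List::create(_["alpha"] = A, _["beta"] = B);
}
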