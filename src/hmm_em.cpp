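#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dnorm_safe(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  double d = std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
  return d < 1e-300 ? 1e-300 : d;
}

// Scaled forward-backward for a 2-state Gaussian HMM.
// Fills gamma (n x 2) and xi (2 x 2 expected transition counts);
// returns the log-likelihood.
static double forward_backward(const NumericVector& x,
                               const double mu[2], const double sd[2],
                               const double A[2][2], const double pi0[2],
                               NumericMatrix& gamma, double xi[2][2]) {
  int n = x.size();
  std::vector<double> a0(n), a1(n), b0(n), b1(n), c(n);
  std::vector<double> e0(n), e1(n);
  for (int t = 0; t < n; ++t) {
    e0[t] = dnorm_safe(x[t], mu[0], sd[0]);
    e1[t] = dnorm_safe(x[t], mu[1], sd[1]);
  }
  double u0 = pi0[0] * e0[0], u1 = pi0[1] * e1[0];
  c[0] = u0 + u1;
  a0[0] = u0 / c[0]; a1[0] = u1 / c[0];
  for (int t = 1; t < n; ++t) {
    u0 = (a0[t-1] * A[0][0] + a1[t-1] * A[1][0]) * e0[t];
    u1 = (a0[t-1] * A[0][1] + a1[t-1] * A[1][1]) * e1[t];
    c[t] = u0 + u1;
    a0[t] = u0 / c[t]; a1[t] = u1 / c[t];
  }
  b0[n-1] = 1.0; b1[n-1] = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    double w0 = e0[t+1] * b0[t+1], w1 = e1[t+1] * b1[t+1];
    b0[t] = (A[0][0] * w0 + A[0][1] * w1) / c[t+1];
    b1[t] = (A[1][0] * w0 + A[1][1] * w1) / c[t+1];
  }
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    double g0 = a0[t] * b0[t], g1 = a1[t] * b1[t];
    double s = g0 + g1;
    gamma(t, 0) = g0 / s; gamma(t, 1) = g1 / s;
    ll += std::log(c[t]);
  }
  xi[0][0] = xi[0][1] = xi[1][0] = xi[1][1] = 0.0;
  for (int t = 0; t < n - 1; ++t) {
    double w0 = e0[t+1] * b0[t+1] / c[t+1], w1 = e1[t+1] * b1[t+1] / c[t+1];
    xi[0][0] += a0[t] * A[0][0] * w0;
    xi[0][1] += a0[t] * A[0][1] * w1;
    xi[1][0] += a1[t] * A[1][0] * w0;
    xi[1][1] += a1[t] * A[1][1] * w1;
  }
  return ll;
}

// [[Rcpp::export(name = ".hmm_em_cpp")]]
List hmm_em_cpp(NumericVector x, NumericVector mu_init, NumericVector sd_init,
                NumericMatrix A_init, NumericVector pi_init,
                int max_iter, double tol, double sd_floor) {
  int n = x.size();
  double mu[2] = {mu_init[0], mu_init[1]};
  double sd[2] = {sd_init[0], sd_init[1]};
  double A[2][2] = {{A_init(0,0), A_init(0,1)}, {A_init(1,0), A_init(1,1)}};
  double pi0[2] = {pi_init[0], pi_init[1]};
  NumericMatrix gamma(n, 2);
  double xi[2][2];
  double prev_ll = R_NegInf, ll = R_NegInf;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    ll = forward_backward(x, mu, sd, A, pi0, gamma, xi);
    // M step
    for (int i = 0; i < 2; ++i) {
      double rs = xi[i][0] + xi[i][1];
      if (rs > 0) { A[i][0] = xi[i][0] / rs; A[i][1] = xi[i][1] / rs; }
    }
    double w0 = 0, w1 = 0, m0 = 0, m1 = 0;
    for (int t = 0; t < n; ++t) {
      w0 += gamma(t, 0); w1 += gamma(t, 1);
      m0 += gamma(t, 0) * x[t]; m1 += gamma(t, 1) * x[t];
    }
    double mu0 = m0 / w0, mu1 = m1 / w1;
    double v0 = 0, v1 = 0;
    for (int t = 0; t < n; ++t) {
      double d0 = x[t] - mu0, d1 = x[t] - mu1;
      v0 += gamma(t, 0) * d0 * d0;
      v1 += gamma(t, 1) * d1 * d1;
    }
    mu[0] = mu0; mu[1] = mu1;
    sd[0] = std::max(std::sqrt(v0 / w0), sd_floor);
    sd[1] = std::max(std::sqrt(v1 / w1), sd_floor);
    // keep the enriched (higher-mean) state at least as dispersed as the
    // background state: a thin high state would otherwise hand its own
    // far tail back to the background component
    if (mu[1] >= mu[0] && sd[1] < sd[0]) sd[1] = sd[0];
    else if (mu[0] > mu[1] && sd[0] < sd[1]) sd[0] = sd[1];
    pi0[0] = gamma(0, 0); pi0[1] = gamma(0, 1);
    if (R_finite(prev_ll) && std::fabs(ll - prev_ll) < tol) break;
    prev_ll = ll;
  }
  // final posterior under the fitted parameters
  ll = forward_backward(x, mu, sd, A, pi0, gamma, xi);
  return List::create(
    _["mu"] = NumericVector::create(mu[0], mu[1]),
    _["sd"] = NumericVector::create(sd[0], sd[1]),
    _["A"] = NumericMatrix(2, 2,
                           std::vector<double>{A[0][0], A[1][0],
                                               A[0][1], A[1][1]}.data()),
    _["pi0"] = NumericVector::create(pi0[0], pi0[1]),
    _["gamma"] = gamma,
    _["loglik"] = ll,
    _["iterations"] = iter);
}

// [[Rcpp::export(name = ".hmm_posterior_cpp")]]
NumericMatrix hmm_posterior_cpp(NumericVector x, NumericVector mu_in,
                                NumericVector sd_in, NumericMatrix A_in,
                                NumericVector pi_in) {
  int n = x.size();
  double mu[2] = {mu_in[0], mu_in[1]};
  double sd[2] = {sd_in[0], sd_in[1]};
  double A[2][2] = {{A_in(0,0), A_in(0,1)}, {A_in(1,0), A_in(1,1)}};
  double pi0[2] = {pi_in[0], pi_in[1]};
  NumericMatrix gamma(n, 2);
  double xi[2][2];
  forward_backward(x, mu, sd, A, pi0, gamma, xi);
  return gamma;
}
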