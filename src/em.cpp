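// EM inner loop for univariate Gaussian mixtures with an optional
// inverse-gamma MAP penalty on component variances. Called per start from
// fit_gaussian_mixture(); all model logic (initialisation, restarts,
// sorting, BIC) stays in R.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG_2PI_HALF = 0.91893853320467274178;

// penalized objective: loglik - sum_k [ beta/(2 s_k^2) + (lambda/2) log s_k^2 ]
static double penalty(const std::vector<double>& sd, double lambda, double beta) {
  if (lambda == 0.0 && beta == 0.0) return 0.0;
  double p = 0.0;
  for (double s : sd) p += -beta / (2.0 * s * s) - lambda * std::log(s);
  return p;
}

// [[Rcpp::export(name = ".em_run_cpp")]]
List em_run_cpp(NumericVector x, NumericVector w0, NumericVector mu0,
                NumericVector sd0, double lambda, double beta,
                double tol, int max_iter, double sd_floor,
                bool allow_floor) {
  const int n = x.size();
  const int K = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  std::vector<double> r(n * K);
  std::vector<double> trace;
  trace.reserve(64);
  double obj = R_NegInf, obj_prev = R_NegInf;
  bool converged = false, degenerate = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    // E-step: responsibilities and log-likelihood
    double loglik = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double z = (x[i] - mu[k]) / sd[k];
        double l = std::log(w[k]) - LOG_2PI_HALF - std::log(sd[k]) - 0.5 * z * z;
        r[i * K + k] = l;
        if (l > mx) mx = l;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(r[i * K + k] - mx);
      double lse = mx + std::log(s);
      loglik += lse;
      for (int k = 0; k < K; ++k) r[i * K + k] = std::exp(r[i * K + k] - lse);
    }
    obj = loglik + penalty(sd, lambda, beta);
    trace.push_back(obj);
    if (std::isfinite(obj_prev) &&
        std::fabs(obj - obj_prev) < tol * (1.0 + std::fabs(obj))) {
      converged = true;
      break;
    }
    obj_prev = obj;
    // M-step
    for (int k = 0; k < K; ++k) {
      double Nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) { Nk += r[i * K + k]; sx += r[i * K + k] * x[i]; }
      if (Nk < 1e-8) { degenerate = true; break; }
      double m = sx / Nk;
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - m;
        ss += r[i * K + k] * d * d;
      }
      double v = (ss + beta) / (Nk + lambda);
      double s = std::sqrt(v);
      if (s < sd_floor) {
        s = sd_floor;
        if (!allow_floor) { degenerate = true; }
      }
      w[k] = Nk / n;
      mu[k] = m;
      sd[k] = s;
    }
    if (degenerate) break;
  }

  return List::create(
    _["w"] = NumericVector(w.begin(), w.end()),
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["sd"] = NumericVector(sd.begin(), sd.end()),
    _["objective"] = obj,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["converged"] = converged,
    _["degenerate"] = degenerate);
}
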