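#include <Rcpp.h>
using namespace Rcpp;

// EM for a univariate Gaussian mixture with fixed k.
//
// Responsibilities are computed with a log-sum-exp E-step so that widely
// separated components do not underflow.  `sd_floor` is an absolute lower
// bound on component standard deviations, applied at every M-step to guard
// against single-point collapse.  Convergence: relative change in the
// log-likelihood below `tol` (checked from the second iteration on).
//
// [[Rcpp::export]]
List em_gauss_cpp(NumericVector x, NumericVector w0, NumericVector mu0,
                  NumericVector sd0, double tol, int max_iter,
                  double sd_floor) {
  const int n = x.size(), k = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  NumericMatrix resp(n, k);
  std::vector<double> trace;
  trace.reserve(64);
  const double LOG2PI = std::log(2.0 * M_PI);
  double ll = R_NegInf, ll_prev = R_NegInf;
  bool converged = false;
  int iter = 0;

  while (iter < max_iter) {
    ++iter;
    // E-step
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      for (int j = 0; j < k; ++j) {
        double z = (x[i] - mu[j]) / sd[j];
        double lw = std::log(w[j]) - std::log(sd[j]) - 0.5 * (LOG2PI + z * z);
        resp(i, j) = lw;
        if (lw > m) m = lw;
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += std::exp(resp(i, j) - m);
      ll += m + std::log(s);
      for (int j = 0; j < k; ++j) resp(i, j) = std::exp(resp(i, j) - m) / s;
    }
    trace.push_back(ll);
    if (iter > 1 &&
        std::fabs(ll - ll_prev) < tol * std::max(1.0, std::fabs(ll_prev))) {
      converged = true;
      break;
    }
    ll_prev = ll;
    // M-step
    for (int j = 0; j < k; ++j) {
      double nj = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) {
        nj += resp(i, j);
        sx += resp(i, j) * x[i];
      }
      if (nj < 1e-300) nj = 1e-300;
      double mj = sx / nj, ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - mj;
        ss += resp(i, j) * d * d;
      }
      w[j] = nj / n;
      mu[j] = mj;
      sd[j] = std::max(std::sqrt(ss / nj), sd_floor);
    }
  }

  return List::create(
      _["weight"] = NumericVector(w.begin(), w.end()),
      _["mean"] = NumericVector(mu.begin(), mu.end()),
      _["sd"] = NumericVector(sd.begin(), sd.end()), _["loglik"] = ll,
      _["n_iter"] = iter, _["converged"] = converged,
      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
      _["responsibilities"] = resp);
}
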