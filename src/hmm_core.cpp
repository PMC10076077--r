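#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass.
//
// logdens: N x k matrix of per-sample emission log-densities (0 for missing
// samples, so they are driven by the transition structure alone).
// Returns posteriors gamma (N x k), the summed transition posteriors
// xi_sum (k x k, sum over t of P(S_t = i, S_{t+1} = j | data)), and the
// marginal log-likelihood.
//
// Row maxima of logdens are factored out before exponentiation so that
// extreme emission terms (saccade-range velocities under a fixation state)
// cannot underflow the scaled recursion.
// [[Rcpp::export]]
List hmm_estep_cpp(NumericMatrix logdens, NumericVector rho, NumericMatrix A) {
  const int N = logdens.nrow(), k = logdens.ncol();
  NumericMatrix b(N, k);
  NumericVector m(N);
  for (int t = 0; t < N; ++t) {
    double mx = logdens(t, 0);
    for (int j = 1; j < k; ++j) if (logdens(t, j) > mx) mx = logdens(t, j);
    m[t] = mx;
    for (int j = 0; j < k; ++j) b(t, j) = std::exp(logdens(t, j) - mx);
  }

  NumericMatrix alpha(N, k), beta(N, k);
  NumericVector c(N);
  double ll = 0.0;

  double s = 0.0;
  for (int j = 0; j < k; ++j) { alpha(0, j) = rho[j] * b(0, j); s += alpha(0, j); }
  if (!(s > 0.0)) stop("forward recursion underflow at t = 1");
  c[0] = s;
  for (int j = 0; j < k; ++j) alpha(0, j) /= s;
  ll += std::log(s) + m[0];

  for (int t = 1; t < N; ++t) {
    s = 0.0;
    for (int j = 0; j < k; ++j) {
      double a = 0.0;
      for (int i = 0; i < k; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= b(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (!(s > 0.0)) stop("forward recursion underflow at t = %d", t + 1);
    c[t] = s;
    for (int j = 0; j < k; ++j) alpha(t, j) /= s;
    ll += std::log(s) + m[t];
  }

  for (int j = 0; j < k; ++j) beta(N - 1, j) = 1.0;
  for (int t = N - 2; t >= 0; --t) {
    for (int i = 0; i < k; ++i) {
      double v = 0.0;
      for (int j = 0; j < k; ++j) v += A(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = v / c[t + 1];
    }
  }

  NumericMatrix gamma(N, k);
  for (int t = 0; t < N; ++t) {
    double g = 0.0;
    for (int j = 0; j < k; ++j) { gamma(t, j) = alpha(t, j) * beta(t, j); g += gamma(t, j); }
    for (int j = 0; j < k; ++j) gamma(t, j) /= g;
  }

  NumericMatrix xi(k, k);
  for (int t = 0; t < N - 1; ++t)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        xi(i, j) += alpha(t, i) * A(i, j) * b(t + 1, j) * beta(t + 1, j) / c[t + 1];

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi, _["loglik"] = ll);
}

// Marginal log-likelihood only (scaled forward recursion).
// [[Rcpp::export]]
double hmm_loglik_cpp(NumericMatrix logdens, NumericVector rho, NumericMatrix A) {
  const int N = logdens.nrow(), k = logdens.ncol();
  std::vector<double> prev(k), cur(k);
  double ll = 0.0;

  double mx = logdens(0, 0);
  for (int j = 1; j < k; ++j) if (logdens(0, j) > mx) mx = logdens(0, j);
  double s = 0.0;
  for (int j = 0; j < k; ++j) { prev[j] = rho[j] * std::exp(logdens(0, j) - mx); s += prev[j]; }
  if (!(s > 0.0)) stop("forward recursion underflow at t = 1");
  for (int j = 0; j < k; ++j) prev[j] /= s;
  ll += std::log(s) + mx;

  for (int t = 1; t < N; ++t) {
    mx = logdens(t, 0);
    for (int j = 1; j < k; ++j) if (logdens(t, j) > mx) mx = logdens(t, j);
    s = 0.0;
    for (int j = 0; j < k; ++j) {
      double a = 0.0;
      for (int i = 0; i < k; ++i) a += prev[i] * A(i, j);
      cur[j] = a * std::exp(logdens(t, j) - mx);
      s += cur[j];
    }
    if (!(s > 0.0)) stop("forward recursion underflow at t = %d", t + 1);
    for (int j = 0; j < k; ++j) prev[j] = cur[j] / s;
    ll += std::log(s) + mx;
  }
  return ll;
}

// Viterbi decoding in log space. Ties are broken toward the lower state
// index (strict > comparison keeps the first maximum).
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logdens, NumericVector rho, NumericMatrix A) {
  const int N = logdens.nrow(), k = logdens.ncol();
  NumericMatrix delta(N, k);
  IntegerMatrix psi(N, k);
  for (int j = 0; j < k; ++j)
    delta(0, j) = (rho[j] > 0 ? std::log(rho[j]) : R_NegInf) + logdens(0, j);

  std::vector<double> logA(k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      logA[i * k + j] = A(i, j) > 0 ? std::log(A(i, j)) : R_NegInf;

  for (int t = 1; t < N; ++t) {
    for (int j = 0; j < k; ++j) {
      double best = delta(t - 1, 0) + logA[j];
      int arg = 0;
      for (int i = 1; i < k; ++i) {
        double v = delta(t - 1, i) + logA[i * k + j];
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logdens(t, j);
      psi(t, j) = arg;
    }
  }

  IntegerVector path(N);
  int arg = 0;
  double best = delta(N - 1, 0);
  for (int j = 1; j < k; ++j) if (delta(N - 1, j) > best) { best = delta(N - 1, j); arg = j; }
  path[N - 1] = arg + 1;
  for (int t = N - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
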