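#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward pass.  alpha is renormalized at every step; scale[t] holds
// the normalizer, so log P(O | lambda) = sum(log(scale)).  A symbol with zero
// emission mass in every state makes the likelihood exactly zero: we report
// loglik = -Inf and fill the remaining rows with a uniform placeholder rather
// than throwing, so callers can score impossible sequences.
// [[Rcpp::export(name = ".forward_cpp")]]
List forward_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B,
                 IntegerVector obs) {
  const int N = pi.size(), T = obs.size();
  NumericMatrix alpha(T, N);
  NumericVector scale(T);
  double ll = 0.0;
  bool dead = false;
  for (int t = 0; t < T; ++t) {
    const int k = obs[t] - 1;
    double c = 0.0;
    if (t == 0) {
      for (int i = 0; i < N; ++i) {
        alpha(0, i) = pi[i] * B(i, k);
        c += alpha(0, i);
      }
    } else {
      for (int j = 0; j < N; ++j) {
        double s = 0.0;
        for (int i = 0; i < N; ++i) s += alpha(t - 1, i) * A(i, j);
        alpha(t, j) = s * B(j, k);
        c += alpha(t, j);
      }
    }
    if (dead || c <= 0.0) {
      dead = true;
      for (int i = 0; i < N; ++i) alpha(t, i) = 1.0 / N;
      scale[t] = 1.0;
    } else {
      for (int i = 0; i < N; ++i) alpha(t, i) /= c;
      scale[t] = c;
      ll += std::log(c);
    }
  }
  if (dead) ll = R_NegInf;
  return List::create(_["alpha"] = alpha, _["scale"] = scale,
                      _["loglik"] = ll);
}

// Backward pass under the forward scaling factors: beta_hat_T = 1 and
// beta_hat_t(i) = sum_j A(i,j) B(j, o_{t+1}) beta_hat_{t+1}(j) / scale[t+1].
// With this convention sum_i alpha_hat_t(i) beta_hat_t(i) = 1 for all t.
// [[Rcpp::export(name = ".backward_cpp")]]
NumericMatrix backward_cpp(NumericMatrix A, NumericMatrix B,
                           IntegerVector obs, NumericVector scale) {
  const int N = A.nrow(), T = obs.size();
  NumericMatrix beta(T, N);
  for (int i = 0; i < N; ++i) beta(T - 1, i) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const int k = obs[t + 1] - 1;
    const double c = scale[t + 1];
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int j = 0; j < N; ++j) s += A(i, j) * B(j, k) * beta(t + 1, j);
      beta(t, i) = (c > 0.0) ? s / c : 0.0;
    }
  }
  return beta;
}

// One E-step over a single sequence: forward, backward, then accumulate the
// expected-count numerators and denominators of the Baum-Welch update.
//   xi_t(i,j)   = alpha_hat_t(i) A(i,j) B(j,o_{t+1}) beta_hat_{t+1}(j)/c_{t+1}
//   gamma_t(i)  = alpha_hat_t(i) beta_hat_t(i)
// Returns sums ready for pooling across sequences.
// [[Rcpp::export(name = ".bw_accumulate_cpp")]]
List bw_accumulate_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B,
                       IntegerVector obs) {
  const int N = pi.size(), M = B.ncol(), T = obs.size();
  List fw = forward_cpp(pi, A, B, obs);
  double ll = fw["loglik"];
  NumericMatrix alpha = fw["alpha"];
  NumericVector scale = fw["scale"];
  NumericMatrix A_num(N, N), B_num(N, M);
  NumericVector A_den(N), B_den(N), gamma1(N);
  if (!R_FINITE(ll)) {
    return List::create(_["loglik"] = ll, _["ok"] = false,
                        _["A_num"] = A_num, _["A_den"] = A_den,
                        _["B_num"] = B_num, _["B_den"] = B_den,
                        _["gamma1"] = gamma1);
  }
  NumericMatrix beta = backward_cpp(A, B, obs, scale);
  for (int t = 0; t < T; ++t) {
    const int k = obs[t] - 1;
    for (int i = 0; i < N; ++i) {
      const double g = alpha(t, i) * beta(t, i);
      if (t == 0) gamma1[i] = g;
      B_num(i, k) += g;
      B_den[i] += g;
      if (t < T - 1) A_den[i] += g;
    }
    if (t < T - 1) {
      const int k1 = obs[t + 1] - 1;
      const double c1 = scale[t + 1];
      for (int i = 0; i < N; ++i) {
        for (int j = 0; j < N; ++j) {
          A_num(i, j) += alpha(t, i) * A(i, j) * B(j, k1) * beta(t + 1, j) / c1;
        }
      }
    }
  }
  return List::create(_["loglik"] = ll, _["ok"] = true,
                      _["A_num"] = A_num, _["A_den"] = A_den,
                      _["B_num"] = B_num, _["B_den"] = B_den,
                      _["gamma1"] = gamma1);
}
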