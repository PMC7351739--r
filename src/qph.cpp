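#include <Rcpp.h>
using namespace Rcpp;

// Q-PH model family: hybrid Rescorla-Wagner / Pearce-Hall Q-learning.
// model codes: 1 = two learning rates (kappa1, kappa2, eta, beta)
//              2 = two associability rates (kappa, eta1, eta2, beta)
//              3 = forgetting (kappaL, kappaF, eta, beta)
// States s and actions a are 1-based {1,2}; action 1 = lick, 2 = restrain.
// Q(s,a) initialised at 0.5, associabilities at 0.

static inline double softmax_logp(double qa, double qb, double beta) {
  // log P(chosen | Q) with chosen-action value qa, overflow-safe
  double m = std::max(qa, qb) * beta;
  double za = std::exp(beta * qa - m), zb = std::exp(beta * qb - m);
  return (beta * qa - m) - std::log(za + zb);
}

// [[Rcpp::export]]
double qph_loglik_cpp(int model, IntegerVector s, IntegerVector a,
                      NumericVector r, NumericVector theta) {
  int n = s.size();
  double Q[2][2] = {{0.5, 0.5}, {0.5, 0.5}};
  double alpha = 0.0, alphaF = 0.0;
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int si = s[t] - 1, ai = a[t] - 1, ao = 1 - ai;
    ll += softmax_logp(Q[si][ai], Q[si][ao], theta[3]);
    double delta = r[t] - Q[si][ai];
    if (model == 1) {          // kappa1, kappa2, eta, beta
      double kap = (ai == 0) ? theta[0] : theta[1];
      Q[si][ai] += kap * alpha * delta;
      alpha = (1.0 - theta[2]) * alpha + theta[2] * std::fabs(delta);
    } else if (model == 2) {   // kappa, eta1, eta2, beta
      double eta = (ai == 0) ? theta[1] : theta[2];
      Q[si][ai] += theta[0] * alpha * delta;
      alpha = (1.0 - eta) * alpha + eta * std::fabs(delta);
    } else {                   // kappaL, kappaF, eta, beta
      double eta = theta[2];
      Q[si][ai] += theta[0] * alpha * delta;
      alpha = (1.0 - eta) * alpha + eta * std::fabs(delta);
      double qo = Q[si][ao];
      Q[si][ao] = qo - theta[1] * alphaF * qo;
      alphaF = (1.0 - eta) * alphaF + eta * qo;
    }
  }
  return ll;
}

// [[Rcpp::export]]
List qph_traces_cpp(int model, IntegerVector s, IntegerVector a,
                    NumericVector r, NumericVector theta,
                    IntegerVector cs_state) {
  int n = s.size();
  NumericMatrix Qt(n, 4);      // columns: Q(1,1) Q(1,2) Q(2,1) Q(2,2), pre-update
  NumericVector alpha_t(n), alphaF_t(n), delta_t(n), v_t(n), logp(n);
  double Q[2][2] = {{0.5, 0.5}, {0.5, 0.5}};
  double alpha = 0.0, alphaF = 0.0;
  for (int t = 0; t < n; ++t) {
    int si = s[t] - 1, ai = a[t] - 1, ao = 1 - ai;
    Qt(t, 0) = Q[0][0]; Qt(t, 1) = Q[0][1]; Qt(t, 2) = Q[1][0]; Qt(t, 3) = Q[1][1];
    alpha_t[t] = alpha; alphaF_t[t] = alphaF;
    int ci = cs_state[t] - 1;
    v_t[t] = std::max(Q[ci][0], Q[ci][1]);
    logp[t] = softmax_logp(Q[si][ai], Q[si][ao], theta[3]);
    double delta = r[t] - Q[si][ai];
    delta_t[t] = delta;
    if (model == 1) {
      double kap = (ai == 0) ? theta[0] : theta[1];
      Q[si][ai] += kap * alpha * delta;
      alpha = (1.0 - theta[2]) * alpha + theta[2] * std::fabs(delta);
    } else if (model == 2) {
      double eta = (ai == 0) ? theta[1] : theta[2];
      Q[si][ai] += theta[0] * alpha * delta;
      alpha = (1.0 - eta) * alpha + eta * std::fabs(delta);
    } else {
      double eta = theta[2];
      Q[si][ai] += theta[0] * alpha * delta;
      alpha = (1.0 - eta) * alpha + eta * std::fabs(delta);
      double qo = Q[si][ao];
      Q[si][ao] = qo - theta[1] * alphaF * qo;
      alphaF = (1.0 - eta) * alphaF + eta * qo;
    }
  }
  return List::create(_["Q"] = Qt, _["alpha"] = alpha_t, _["alpha_F"] = alphaF_t,
                      _["delta"] = delta_t, _["value_cs"] = v_t,
                      _["logp"] = logp);
}

// Coincidence counts C(l) = sum_k min(a_k, b_{k+l}) for each lag l in `lags`
// (0-based offsets applied to b). Summation restricted to k in [k0, k1]
// (1-based, inclusive) so every lag uses the same number of terms.
// [[Rcpp::export]]
NumericVector coincidence_counts_cpp(IntegerVector a, IntegerVector b,
                                     IntegerVector lags, int k0, int k1) {
  int nl = lags.size();
  int nb = b.size();
  NumericVector out(nl);
  for (int j = 0; j < nl; ++j) {
    int l = lags[j];
    double c = 0.0;
    for (int k = k0 - 1; k <= k1 - 1; ++k) {
      int kb = k + l;
      if (kb < 0 || kb >= nb) continue;
      c += std::min(a[k], b[kb]);
    }
    out[j] = c;
  }
  return out;
}
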