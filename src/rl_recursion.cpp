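#include <Rcpp.h>
using namespace Rcpp;

// Forward recursion for the two-armed bandit value-learning models.
//
// Inputs are one subject x one condition, in trial order:
//   chosen    : 1 or 2 (option A / B)
//   outcome   : signed outcome in dollars
//   is_large  : 1 if |outcome| is the block pair's large magnitude
//   new_block : 1 on the first trial of each block (state reset)
//
// Parameters: alpha (learning rate), eta (associability weight),
// rho (sensitivity multiplier on the large-magnitude outcome),
// gamma (decay of the unchosen option), beta (inverse temperature).
// variant: 0 = basic delta-rule, 1 = associability-gated learning rate.
// rho_all: 1 applies rho to both outcomes instead of the large one only.
//
// State per block: Q starts at (0, 0); associability kappa starts at (1, 1)
// and is floored at 0.05 after every update. The choice probability on a
// trial uses the Q values produced by all updates through the previous
// trial; recorded latents are the pre-update values at the outcome event.

static const double KAPPA_FLOOR = 0.05;

// log(1/(1+exp(-d))) computed stably
static inline double log_logistic(double d) {
  if (d > 0) {
    return -log1p(std::exp(-d));
  } else {
    return d - log1p(std::exp(d));
  }
}

// [[Rcpp::export]]
List cpp_rl_forward(IntegerVector chosen, NumericVector outcome,
                    IntegerVector is_large, IntegerVector new_block,
                    double alpha, double eta, double rho, double gamma,
                    double beta, int variant, int rho_all, int want_trace) {
  const int n = chosen.size();
  double Q[2] = {0.0, 0.0};
  double K[2] = {1.0, 1.0};
  double nll = 0.0;

  NumericVector tr_Qc, tr_Qu, tr_K, tr_delta, tr_p, tr_R;
  if (want_trace) {
    tr_Qc = NumericVector(n); tr_Qu = NumericVector(n);
    tr_K = NumericVector(n);  tr_delta = NumericVector(n);
    tr_p = NumericVector(n);  tr_R = NumericVector(n);
  }

  for (int t = 0; t < n; ++t) {
    if (new_block[t]) {
      Q[0] = 0.0; Q[1] = 0.0;
      K[0] = 1.0; K[1] = 1.0;
    }
    const int ch = chosen[t] - 1;
    if (ch < 0 || ch > 1) stop("invalid choice code at trial %d", t + 1);
    const int un = 1 - ch;

    const double lp = log_logistic(beta * (Q[ch] - Q[un]));
    nll -= lp;

    const double Rp = (rho_all || is_large[t]) ? rho * outcome[t] : outcome[t];
    const double delta = Rp - Q[ch];

    if (want_trace) {
      tr_Qc[t] = Q[ch]; tr_Qu[t] = Q[un]; tr_K[t] = K[ch];
      tr_delta[t] = delta; tr_p[t] = std::exp(lp); tr_R[t] = Rp;
    }

    if (variant) {
      Q[ch] += alpha * K[ch] * delta;
      K[ch] = (1.0 - eta) * K[ch] + eta * std::fabs(delta);
      if (K[ch] < KAPPA_FLOOR) K[ch] = KAPPA_FLOOR;
    } else {
      Q[ch] += alpha * delta;
    }
    Q[un] *= gamma;
  }

  if (want_trace) {
    return List::create(_["nll"] = nll, _["Q_chosen"] = tr_Qc,
                        _["Q_unchosen"] = tr_Qu, _["kappa_chosen"] = tr_K,
                        _["delta"] = tr_delta, _["p_chosen"] = tr_p,
                        _["scaled_outcome"] = tr_R);
  }
  return List::create(_["nll"] = nll);
}
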