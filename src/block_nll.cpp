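#include <Rcpp.h>
using namespace Rcpp;

// log(1/(1+exp(-x))) without overflow/underflow
static inline double log_sigmoid(double x) {
  if (x > 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// Teacher-forced negative log-likelihood of one block of choices under the
// delta-rule Q-learning model with softmax choice and (for social blocks) a
// one-time value boost toward a ceiling plus a one-time precision replacement
// applied after the feedback of trial `cue_after` and before the next choice.
//
// trial   : original 1-based trial indices (gaps allowed after RT filtering)
// choice  : chosen lake, 0 or 1
// reward  : realised yield on the chosen lake
// social  : whether the block carries a social cue
// cue_target : lake indicated by the cue (0/1); ignored when !social
// ceiling_observed : TRUE -> boost ceiling is the largest reward observed in
//                    the block before the cue, floored at q_init (Q-values
//                    are convex combinations of q_init and rewards, so this
//                    ceiling weakly dominates both lakes' values and a full
//                    boost always reaches the "maximum level");
//                    FALSE -> the fixed ceiling q_fixed
// [[Rcpp::export]]
double block_nll_cpp(IntegerVector trial, IntegerVector choice,
                     NumericVector reward,
                     bool social, int cue_target, int cue_after,
                     double alpha, double beta,
                     double qboost, double bboost,
                     double q_init, bool ceiling_observed, double q_fixed) {
  int n = choice.size();
  if (n == 0) stop("empty block");
  double q[2] = {q_init, q_init};
  double b = beta;
  bool boosted = false;
  double rmax = R_NegInf;
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (social && !boosted && trial[i] > cue_after) {
      double qmax = ceiling_observed
                      ? (R_finite(rmax) ? std::max(rmax, q_init) : q_init)
                      : q_fixed;
      q[cue_target] = (1.0 - qboost) * q[cue_target] + qboost * qmax;
      b = bboost;
      boosted = true;
    }
    int c = choice[i];
    nll -= log_sigmoid(b * (q[c] - q[1 - c]));
    double r = reward[i];
    if (r > rmax) rmax = r;
    q[c] += alpha * (r - q[c]);
  }
  return nll;
}
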