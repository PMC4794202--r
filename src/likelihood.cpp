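#include <Rcpp.h>
using namespace Rcpp;

// Session negative log-likelihood of the seven-parameter hybrid agent.
// par: alpha1, alpha2, lam, beta2, beta_hb, beta_gd, p (natural scale).
// Trials with any NA field are skipped from likelihood and learning.
// [[Rcpp::export]]
double nll_session_cpp(IntegerVector choice1, IntegerVector state2,
                       IntegerVector choice2, NumericVector reward,
                       NumericVector par, double common_prob, double q_init) {
  const int n = choice1.size();
  if (state2.size() != n || choice2.size() != n || reward.size() != n)
    stop("trial columns must have equal length");
  if (par.size() != 7) stop("expected 7 parameters");
  const double a1 = par[0], a2 = par[1], lam = par[2], b2 = par[3],
               bhb = par[4], bgd = par[5], pstick = par[6];

  // trans[a][s]: action 0 commonly reaches state 0, action 1 state 1
  double trans[2][2] = {{common_prob, 1.0 - common_prob},
                        {1.0 - common_prob, common_prob}};
  double qmf1[2] = {q_init, q_init};
  double q2[2][2] = {{q_init, q_init}, {q_init, q_init}};
  int prev = -1;
  double nll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (IntegerVector::is_na(choice1[t]) || IntegerVector::is_na(state2[t]) ||
        IntegerVector::is_na(choice2[t]) || NumericVector::is_na(reward[t]))
      continue;
    const int c1 = choice1[t], s2 = state2[t], c2 = choice2[t];
    const double r = reward[t];

    // model-based stage-1 values: Bellman backup through fixed transitions
    const double max0 = q2[0][0] > q2[0][1] ? q2[0][0] : q2[0][1];
    const double max1 = q2[1][0] > q2[1][1] ? q2[1][0] : q2[1][1];
    double u[2];
    for (int a = 0; a < 2; ++a) {
      const double qmb = trans[a][0] * max0 + trans[a][1] * max1;
      u[a] = bhb * qmf1[a] + bgd * qmb + (a == prev ? pstick : 0.0);
    }
    // log softmax in max-shifted coordinates; never re-add the shift, so
    // the result stays exact even when utilities are astronomically large
    const double umax = u[0] > u[1] ? u[0] : u[1];
    const double z0 = u[0] - umax, z1 = u[1] - umax;
    nll -= (c1 == 0 ? z0 : z1) - std::log(std::exp(z0) + std::exp(z1));

    const double v0 = b2 * q2[s2][0], v1 = b2 * q2[s2][1];
    const double vmax = v0 > v1 ? v0 : v1;
    const double w0 = v0 - vmax, w1 = v1 - vmax;
    nll -= (c2 == 0 ? w0 : w1) - std::log(std::exp(w0) + std::exp(w1));

    // SARSA(lambda) update, stage-2 error computed before the q2 write
    const double q2sa = q2[s2][c2];
    qmf1[c1] += a1 * (q2sa - qmf1[c1]);
    const double delta2 = r - q2sa;
    q2[s2][c2] = q2sa + a2 * delta2;
    qmf1[c1] += a1 * lam * delta2;
    prev = c1;
  }
  return nll;
}
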