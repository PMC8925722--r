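#include <Rcpp.h>
using namespace Rcpp;

// Fast forward-pass negative log-likelihood for the five decision models.
//
// model codes: 1 = WSLS, 2 = Q_RPE, 3 = FQ_RPE, 4 = DQ_RPE, 5 = FQ_RPE_CK
// par layout (full vector, only the entries relevant to `model` are read):
//   par[0] alpha, par[1] alpha_k, par[2] alpha_r, par[3] alpha_u,
//   par[4] beta,  par[5] beta_k,  par[6] p_wsls,
//   par[7] dq_unrewarded_toward_zero (0/1 flag)
// choice: 1 = left, 0 = right, NA = miss (no likelihood term, no update).
// session: integer label per trial; agent state resets when the label changes.
//
// Probabilities are floored at 1e-12 before taking logs so that extreme
// inverse temperatures cannot produce -Inf during optimization.

// [[Rcpp::export]]
double nll_forward_cpp(int model, NumericVector par, IntegerVector choice,
                       IntegerVector outcome, IntegerVector session,
                       double q0, double k0) {
  const double floor_p = 1e-12;
  const double alpha = par[0], alpha_k = par[1], alpha_r = par[2],
               alpha_u = par[3], beta = par[4], beta_k = par[5],
               p_wsls = par[6];
  const bool dq_to_zero = par.size() > 7 && par[7] != 0.0;
  const int n = choice.size();

  double nll = 0.0;
  double qL = q0, qR = q0, kL = k0, kR = k0;
  int prev_c = NA_INTEGER, prev_r = NA_INTEGER;
  int cur_sess = (n > 0) ? session[0] : 0;

  for (int i = 0; i < n; ++i) {
    if (session[i] != cur_sess) {
      qL = qR = q0;
      kL = kR = k0;
      prev_c = prev_r = NA_INTEGER;
      cur_sess = session[i];
    }
    const int c = choice[i], r = outcome[i];
    if (c == NA_INTEGER) continue;  // miss trial

    double pL;
    if (model == 1) {  // WSLS
      if (prev_c == NA_INTEGER) {
        pL = 0.5;
      } else {
        const double p_stay = (prev_r == 1) ? p_wsls : 1.0 - p_wsls;
        pL = (prev_c == 1) ? p_stay : 1.0 - p_stay;
      }
    } else {
      const double bk = (model == 5) ? beta_k : 0.0;
      const double wL = beta * qL + bk * kL;
      const double wR = beta * qR + bk * kR;
      const double m = (wL > wR) ? wL : wR;
      const double eL = std::exp(wL - m), eR = std::exp(wR - m);
      pL = eL / (eL + eR);
    }

    double pc = (c == 1) ? pL : 1.0 - pL;
    if (pc < floor_p) pc = floor_p;
    nll -= std::log(pc);

    // state updates
    if (model == 2) {  // Q_RPE: unchosen unchanged
      if (c == 1) qL += alpha * (r - qL); else qR += alpha * (r - qR);
    } else if (model == 3 || model == 5) {  // FQ: unchosen decays
      if (c == 1) { qL += alpha * (r - qL); qR *= (1.0 - alpha); }
      else        { qR += alpha * (r - qR); qL *= (1.0 - alpha); }
      if (model == 5) {
        if (c == 1) { kL += alpha_k * (1.0 - kL); kR *= (1.0 - alpha_k); }
        else        { kR += alpha_k * (1.0 - kR); kL *= (1.0 - alpha_k); }
      }
    } else if (model == 4) {  // DQ_RPE
      const double rate = (r == 1) ? alpha_r : alpha_u;
      const double target = (r == 0 && dq_to_zero) ? 0.0 : 1.0;
      if (c == 1) qL += rate * (target - qL); else qR += rate * (target - qR);
    }
    prev_c = c;
    prev_r = r;
  }
  return nll;
}
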