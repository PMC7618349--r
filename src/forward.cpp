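#include <Rcpp.h>
using namespace Rcpp;

// Fast forward pass over one session for every agent family.
// Family codes: 0 random, 1 wsls, 2 choice_kernel, 3 q, 4 si.
// Q-variant codes: 0 plain, 1 cf_same, 2 cf_diff, 3 forget_reset,
//                  4 forget_gradual, 5 dynamic.
// Parameter vector layout (canonicalized in R; unused slots 0):
//  0 b, 1 eps, 2 alpha_c, 3 beta_c, 4 alpha_r, 5 alpha_ur,
//  6 alpha_cf_r, 7 alpha_cf_ur, 8 beta, 9 delta, 10 kappa_r, 11 kappa_ur,
// 12 gamma_ph, 13 alpha0, 14 c, 15 d, 16 gamma, 17 bias
// Returns n x 5 matrix: p_right, q_left, q_right, belief_R, rpe
// (snapshots are pre-update; rpe = r - Q(chosen) pre-update).
// [[Rcpp::export]]
NumericMatrix agent_forward_cpp(int family, int qvar, bool use_ck,
                                const NumericVector& par,
                                const IntegerVector& choices,
                                const IntegerVector& rewards) {
  const int n = choices.size();
  NumericMatrix out(n, 5);
  double Q0 = 0.5, Q1 = 0.5, CK0 = 0.0, CK1 = 0.0;
  double bL = 0.5, bR = 0.5;              // belief: left-high, right-high
  double assoc = par[13];
  int last_c = -1, last_r = -1;

  const double b = par[0], eps = par[1], alpha_c = par[2], beta_c = par[3];
  const double alpha_r = par[4], alpha_ur = par[5];
  const double acf_r = par[6], acf_ur = par[7];
  const double beta = par[8], delta = par[9];
  const double kap_r = par[10], kap_ur = par[11], gamma_ph = par[12];
  const double cpar = par[14], dpar = par[15], gamma = par[16];
  const double bias = par[17];

  for (int t = 0; t < n; ++t) {
    const int ch = choices[t], rw = rewards[t];
    double pr;                            // p(right)
    switch (family) {
    case 0: pr = b; break;
    case 1:
      if (last_c < 0) pr = 0.5;
      else {
        int stay = (last_r == 1) ? last_c : 1 - last_c;
        pr = (stay == 1) ? 1.0 - eps / 2.0 : eps / 2.0;
      }
      break;
    case 2: pr = 1.0 / (1.0 + std::exp(-beta_c * (CK1 - CK0))); break;
    case 3: {
      double dl = beta * Q0, dr = beta * (Q1 + bias);
      if (use_ck) { dl += beta_c * CK0; dr += beta_c * CK1; }
      pr = 1.0 / (1.0 + std::exp(-(dr - dl)));
      break;
    }
    default: {
      double dl = 10.0 * bL, dr = 10.0 * (bR + bias);
      if (use_ck) { dl += beta_c * CK0; dr += beta_c * CK1; }
      pr = 1.0 / (1.0 + std::exp(-(dr - dl)));
    }
    }
    const double qch = (ch == 1) ? Q1 : Q0;
    out(t, 0) = pr;
    out(t, 1) = Q0; out(t, 2) = Q1;
    out(t, 3) = bR;
    out(t, 4) = rw - qch;

    // ---- updates ----
    if (family == 3) {
      const double rpe = rw - qch;
      if (qvar == 5) {
        const double kap = (rw == 1) ? kap_r : kap_ur;
        if (ch == 1) Q1 += kap * assoc * rpe; else Q0 += kap * assoc * rpe;
        assoc = assoc * (1.0 - gamma_ph) + gamma_ph * std::fabs(rpe);
      } else {
        const double alp = (rw == 1) ? alpha_r : alpha_ur;
        if (ch == 1) Q1 += alp * rpe; else Q0 += alp * rpe;
        if (qvar == 1 || qvar == 2) {
          const double acf = (qvar == 1) ? alp
                             : ((rw == 1) ? acf_r : acf_ur);
          if (ch == 1) Q0 += acf * ((1.0 - rw) - Q0);
          else         Q1 += acf * ((1.0 - rw) - Q1);
        } else if (qvar == 3 || qvar == 4) {
          const double qbar = 0.5 * (Q0 + Q1);
          double* qu = (ch == 1) ? &Q0 : &Q1;
          if (qvar == 3) *qu = qbar;
          else {
            const double q = *qu;
            if (q > qbar) *qu = std::max((1.0 - delta) * q, qbar);
            else if (q < qbar) *qu = std::min((1.0 + delta) * q, qbar);
            else *qu = qbar;
          }
        }
      }
    } else if (family == 4) {
      double likL, likR;
      if (rw == 1) {
        likL = 0.5 + 0.5 * ((ch == 0) ? cpar : -cpar);
        likR = 0.5 + 0.5 * ((ch == 1) ? cpar : -cpar);
      } else {
        likL = 0.5 + 0.5 * ((ch == 0) ? -dpar : dpar);
        likR = 0.5 + 0.5 * ((ch == 1) ? -dpar : dpar);
      }
      double pL = likL * bL, pR = likR * bR;
      const double z = pL + pR;
      pL /= z; pR /= z;
      const double stay = 0.5 + 0.5 * gamma;
      bL = stay * pL + (1.0 - stay) * pR;
      bR = (1.0 - stay) * pL + stay * pR;
    }
    if (family == 2 || use_ck) {
      CK0 += alpha_c * (((ch == 0) ? 1.0 : 0.0) - CK0);
      CK1 += alpha_c * (((ch == 1) ? 1.0 : 0.0) - CK1);
    }
    last_c = ch; last_r = rw;
  }
  return out;
}

// Negative log-likelihood of the observed choices under the model,
// with probabilities floored at `floor_p` before the log.
// [[Rcpp::export]]
double agent_nll_cpp(int family, int qvar, bool use_ck,
                     const NumericVector& par,
                     const IntegerVector& choices,
                     const IntegerVector& rewards,
                     double floor_p) {
  NumericMatrix m = agent_forward_cpp(family, qvar, use_ck, par, choices,
                                      rewards);
  const int n = choices.size();
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    double p = (choices[t] == 1) ? m(t, 0) : 1.0 - m(t, 0);
    if (p < floor_p) p = floor_p;
    nll -= std::log(p);
  }
  return nll;
}
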