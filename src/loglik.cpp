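#include <Rcpp.h>
using namespace Rcpp;

// Trial-replay likelihoods for the two agent families. Parameter vectors
// arrive in fixed order; machines are coded 0 = A, 1 = B; actions 1/2.

static inline void softmax2(double x1, double x2, double beta,
                            double &p1, double &p2) {
  double m = std::max(beta * x1, beta * x2);
  double e1 = std::exp(beta * x1 - m), e2 = std::exp(beta * x2 - m);
  p1 = e1 / (e1 + e2);
  p2 = 1.0 - p1;
}

// params: beta1, beta2, alpha1, alpha2, alpha_T, lam, w, persev
// [[Rcpp::export]]
List flat_loglik_cpp(NumericVector params, IntegerVector a1,
                     IntegerVector machine, IntegerVector a2,
                     IntegerVector reward, double p_common) {
  const double beta1 = params[0], beta2 = params[1], alpha1 = params[2],
               alpha2 = params[3], alphaT = params[4], lam = params[5],
               w = params[6], persev = params[7];
  const int n = a1.size();
  double Q0[2] = {0.0, 0.0};       // MF values at s0
  double Qm[2][2] = {{0.0, 0.0}, {0.0, 0.0}};   // MF values per machine
  double T2[2][2] = {{0.5, 0.5}, {0.5, 0.5}};   // reward model per machine
  int prev = -1;
  NumericVector p1(n), p2(n);
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    int A1 = a1[t] - 1, m = machine[t], A2 = a2[t] - 1, r = reward[t];
    // model-based stage-1 backup through the fixed transitions
    double bestA = std::max(T2[0][0], T2[0][1]);
    double bestB = std::max(T2[1][0], T2[1][1]);
    double qmb0[2] = {p_common * bestA + (1 - p_common) * bestB,
                      (1 - p_common) * bestA + p_common * bestB};
    double qn1 = w * qmb0[0] + (1 - w) * Q0[0];
    double qn2 = w * qmb0[1] + (1 - w) * Q0[1];
    double l1 = beta1 * qn1 + ((prev == 0) ? persev : 0.0);
    double l2 = beta1 * qn2 + ((prev == 1) ? persev : 0.0);
    double mx = std::max(l1, l2);
    double e1 = std::exp(l1 - mx), e2 = std::exp(l2 - mx);
    double pa1 = e1 / (e1 + e2);
    p1[t] = (A1 == 0) ? pa1 : 1.0 - pa1;

    double q21 = w * T2[m][0] + (1 - w) * Qm[m][0];
    double q22 = w * T2[m][1] + (1 - w) * Qm[m][1];
    double pb1, pb2;
    softmax2(q21, q22, beta2, pb1, pb2);
    p2[t] = (A2 == 0) ? pb1 : pb2;
    ll += std::log(p1[t]) + std::log(p2[t]);

    // learning, in the documented order
    T2[m][A2] = (1 - alphaT) * T2[m][A2] + alphaT * r;
    double q2pre = Qm[m][A2];
    Q0[A1] += alpha1 * (q2pre - Q0[A1]);
    double delta2 = r - q2pre;
    Qm[m][A2] = q2pre + alpha2 * delta2;
    Q0[A1] += alpha1 * lam * delta2;
    prev = A1;
  }
  return List::create(_["loglik"] = ll, _["p1"] = p1, _["p2"] = p2);
}

// params: beta1, beta2, alpha_a, alpha_s, kappa, persev
// options indexed 0..5: single1, single2, seq11, seq12, seq21, seq22
// [[Rcpp::export]]
List hier_loglik_cpp(NumericVector params, IntegerVector a1,
                     IntegerVector machine, IntegerVector a2,
                     IntegerVector reward, double p_common, bool lesioned) {
  const double beta1 = params[0], beta2 = params[1], alpha_a = params[2],
               alpha_s = params[3], kappa = params[4], persev = params[5];
  const int n = a1.size();
  double Tseq[4] = {0.5, 0.5, 0.5, 0.5};        // 11, 12, 21, 22
  double Ta2[2][2] = {{0.5, 0.5}, {0.5, 0.5}};
  const int first_key[6] = {0, 1, 0, 0, 1, 1};
  const double is_single[6] = {1, 1, 0, 0, 0, 0};
  int prev = -1;
  NumericVector p1(n), p2(n), rt_pred(n);
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    int A1 = a1[t] - 1, m = machine[t], A2 = a2[t] - 1, r = reward[t];
    double bestA = std::max(Ta2[0][0], Ta2[0][1]);
    double bestB = std::max(Ta2[1][0], Ta2[1][1]);
    double q[6];
    q[0] = p_common * bestA + (1 - p_common) * bestB;
    q[1] = (1 - p_common) * bestA + p_common * bestB;
    q[2] = Tseq[0]; q[3] = Tseq[1]; q[4] = Tseq[2]; q[5] = Tseq[3];

    double logits[6], mx = -1e300;
    for (int o = 0; o < 6; ++o) {
      logits[o] = beta1 * q[o] + kappa * is_single[o] +
                  ((prev >= 0 && first_key[o] == prev) ? persev : 0.0);
      if (logits[o] > mx) mx = logits[o];
    }
    double po[6], tot = 0.0;
    for (int o = 0; o < 6; ++o) { po[o] = std::exp(logits[o] - mx); tot += po[o]; }
    for (int o = 0; o < 6; ++o) po[o] /= tot;

    // P(observed first key) = single + two sequences starting with it
    int sgl = A1, sq1 = 2 + 2 * A1, sq2 = 3 + 2 * A1;   // seq A1->1, A1->2
    double pk = po[sgl] + po[sq1] + po[sq2];
    p1[t] = pk;

    // posterior over the three consistent options
    double ps1 = po[sq1] / pk, ps2 = po[sq2] / pk, psg = po[sgl] / pk;
    double g1, g2;
    softmax2(Ta2[m][0], Ta2[m][1], beta2, g1, g2);
    double pp;
    if (lesioned) {
      pp = (A2 == 0) ? g1 : g2;
    } else {
      pp = ((A2 == 0) ? ps1 : ps2) + psg * ((A2 == 0) ? g1 : g2);
    }
    p2[t] = pp;
    rt_pred[t] = 1.0 - ((A2 == 0) ? ps1 : ps2);
    ll += std::log(pk) + std::log(pp);

    int sq = 2 * A1 + A2;
    Tseq[sq] = (1 - alpha_s) * Tseq[sq] + alpha_s * r;
    Ta2[m][A2] = (1 - alpha_a) * Ta2[m][A2] + alpha_a * r;
    prev = A1;
  }
  return List::create(_["loglik"] = ll, _["p1"] = p1, _["p2"] = p2,
                      _["rt_pred"] = rt_pred);
}
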