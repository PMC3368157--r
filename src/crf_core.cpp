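// Linear-chain CRF core: forward-backward objective/gradient, log-partition
// and Viterbi decoding.  Label and feature ids are 1-based on the R side.
#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF = -DBL_MAX / 4.0;

// emission scores: T x L matrix, score(t, l) = sum of W[f, l] over active
// features f of token t
static NumericMatrix emissions(const List& feat_seq, const NumericMatrix& W) {
  int T = feat_seq.size(), L = W.ncol();
  NumericMatrix S(T, L);
  for (int t = 0; t < T; ++t) {
    IntegerVector fs = feat_seq[t];
    for (int k = 0; k < fs.size(); ++k) {
      int f = fs[k] - 1;
      for (int l = 0; l < L; ++l) S(t, l) += W(f, l);
    }
  }
  return S;
}

static double logsumexp_row(const std::vector<double>& x) {
  double m = NEG_INF;
  for (double v : x) if (v > m) m = v;
  if (m <= NEG_INF / 2) return NEG_INF;
  double s = 0.0;
  for (double v : x) s += std::exp(v - m);
  return m + std::log(s);
}

// forward pass in log space; returns alpha (T x L) and logZ via reference
static NumericMatrix forward_pass(const NumericMatrix& S,
                                  const NumericMatrix& Tr,
                                  const LogicalMatrix& allowed,
                                  const LogicalVector& start_ok,
                                  double& logZ) {
  int T = S.nrow(), L = S.ncol();
  NumericMatrix alpha(T, L);
  for (int l = 0; l < L; ++l)
    alpha(0, l) = start_ok[l] ? S(0, l) : NEG_INF;
  std::vector<double> buf(L);
  for (int t = 1; t < T; ++t)
    for (int l = 0; l < L; ++l) {
      for (int j = 0; j < L; ++j)
        buf[j] = allowed(j, l) ? alpha(t - 1, j) + Tr(j, l) : NEG_INF;
      double lse = logsumexp_row(buf);
      alpha(t, l) = (lse <= NEG_INF / 2) ? NEG_INF : lse + S(t, l);
    }
  std::vector<double> last(L);
  for (int l = 0; l < L; ++l) last[l] = alpha(T - 1, l);
  logZ = logsumexp_row(last);
  return alpha;
}

static NumericMatrix backward_pass(const NumericMatrix& S,
                                   const NumericMatrix& Tr,
                                   const LogicalMatrix& allowed) {
  int T = S.nrow(), L = S.ncol();
  NumericMatrix beta(T, L);
  std::vector<double> buf(L);
  for (int t = T - 2; t >= 0; --t)
    for (int l = 0; l < L; ++l) {
      for (int j = 0; j < L; ++j)
        buf[j] = allowed(l, j) ? Tr(l, j) + S(t + 1, j) + beta(t + 1, j)
                               : NEG_INF;
      beta(t, l) = logsumexp_row(buf);
    }
  return beta;
}

// [[Rcpp::export]]
double crf_logZ_cpp(List feat_seq, NumericMatrix W, NumericMatrix Tr,
                    LogicalMatrix allowed, LogicalVector start_ok) {
  NumericMatrix S = emissions(feat_seq, W);
  double logZ;
  forward_pass(S, Tr, allowed, start_ok, logZ);
  return logZ;
}

// [[Rcpp::export]]
double crf_path_score_cpp(List feat_seq, IntegerVector labels,
                          NumericMatrix W, NumericMatrix Tr,
                          LogicalMatrix allowed, LogicalVector start_ok) {
  NumericMatrix S = emissions(feat_seq, W);
  int T = S.nrow();
  if (!start_ok[labels[0] - 1]) return NEG_INF;
  double sc = S(0, labels[0] - 1);
  for (int t = 1; t < T; ++t) {
    int a = labels[t - 1] - 1, b = labels[t] - 1;
    if (!allowed(a, b)) return NEG_INF;
    sc += Tr(a, b) + S(t, b);
  }
  return sc;
}

// negative conditional log-likelihood and its gradient, summed over a batch
// [[Rcpp::export]]
List crf_negll_grad_cpp(List feats, List labels, NumericMatrix W,
                        NumericMatrix Tr, LogicalMatrix allowed,
                        LogicalVector start_ok) {
  int L = W.ncol(), F = W.nrow();
  NumericMatrix gW(F, L), gT(L, L);
  double negll = 0.0;
  int n = feats.size();
  for (int s = 0; s < n; ++s) {
    List feat_seq = feats[s];
    IntegerVector lab = labels[s];
    int T = feat_seq.size();
    NumericMatrix S = emissions(feat_seq, W);
    double logZ;
    NumericMatrix alpha = forward_pass(S, Tr, allowed, start_ok, logZ);
    NumericMatrix beta = backward_pass(S, Tr, allowed);

    // gold score
    double gold = S(0, lab[0] - 1);
    for (int t = 1; t < T; ++t)
      gold += Tr(lab[t - 1] - 1, lab[t] - 1) + S(t, lab[t] - 1);
    negll += logZ - gold;

    // state marginals -> gW (expected minus empirical feature counts)
    for (int t = 0; t < T; ++t) {
      IntegerVector fs = feat_seq[t];
      for (int l = 0; l < L; ++l) {
        double lp = alpha(t, l) + beta(t, l) - logZ;
        if (lp <= NEG_INF / 2) continue;
        double p = std::exp(lp);
        for (int k = 0; k < fs.size(); ++k) gW(fs[k] - 1, l) += p;
      }
      for (int k = 0; k < fs.size(); ++k) gW(fs[k] - 1, lab[t] - 1) -= 1.0;
    }
    // transition marginals -> gT
    for (int t = 1; t < T; ++t) {
      for (int a = 0; a < L; ++a) {
        if (alpha(t - 1, a) <= NEG_INF / 2) continue;
        for (int b = 0; b < L; ++b) {
          if (!allowed(a, b)) continue;
          double lp = alpha(t - 1, a) + Tr(a, b) + S(t, b) + beta(t, b) - logZ;
          if (lp <= NEG_INF / 2) continue;
          gT(a, b) += std::exp(lp);
        }
      }
      gT(lab[t - 1] - 1, lab[t] - 1) -= 1.0;
    }
  }
  return List::create(_["negll"] = negll, _["gW"] = gW, _["gT"] = gT);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi_cpp(List feat_seq, NumericMatrix W,
                              NumericMatrix Tr, LogicalMatrix allowed,
                              LogicalVector start_ok) {
  NumericMatrix S = emissions(feat_seq, W);
  int T = S.nrow(), L = S.ncol();
  NumericMatrix delta(T, L);
  IntegerMatrix back(T, L);
  for (int l = 0; l < L; ++l)
    delta(0, l) = start_ok[l] ? S(0, l) : NEG_INF;
  for (int t = 1; t < T; ++t)
    for (int l = 0; l < L; ++l) {
      double best = NEG_INF;
      int arg = 0;
      for (int j = 0; j < L; ++j) {   // first maximum wins: declared order
        if (!allowed(j, l)) continue;
        double v = delta(t - 1, j) + Tr(j, l);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, l) = (best <= NEG_INF / 2) ? NEG_INF : best + S(t, l);
      back(t, l) = arg;
    }
  int argT = 0;
  double best = NEG_INF;
  for (int l = 0; l < L; ++l)
    if (delta(T - 1, l) > best) { best = delta(T - 1, l); argT = l; }
  IntegerVector path(T);
  path[T - 1] = argT + 1;
  for (int t = T - 1; t > 0; --t) {
    argT = back(t, argT);
    path[t - 1] = argT + 1;
  }
  return path;
}
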