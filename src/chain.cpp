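// First-order linear-chain dynamic programs.
//
// Conventions shared with the R side:
//  - feats: List of IntegerVector, one per position, 1-based feature ids
//    (ids out of [1, nfeat] are ignored — frozen-indexer drops at test time
//    are handled in R, but we stay defensive).
//  - W: nfeat x L emission weight matrix; Trans: (L+1) x L transition matrix,
//    row L+1 is the begin-of-sequence row.
//  - labels: 1-based label indices.
//  - Ties break toward the lowest label index (strict > when updating).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void emission_row(const IntegerVector& f,
                                const NumericMatrix& W,
                                std::vector<double>& out) {
  const int L = W.ncol();
  const int nfeat = W.nrow();
  for (int l = 0; l < L; ++l) out[l] = 0.0;
  for (int k = 0; k < f.size(); ++k) {
    int id = f[k] - 1;
    if (id < 0 || id >= nfeat) continue;
    for (int l = 0; l < L; ++l) out[l] += W(id, l);
  }
}

// [[Rcpp::export]]
NumericMatrix chain_emissions(List feats, NumericMatrix W) {
  const int N = feats.size(), L = W.ncol();
  NumericMatrix E(N, L);
  std::vector<double> row(L);
  for (int t = 0; t < N; ++t) {
    emission_row(feats[t], W, row);
    for (int l = 0; l < L; ++l) E(t, l) = row[l];
  }
  return E;
}

// [[Rcpp::export]]
double chain_score_path(List feats, IntegerVector labels,
                        NumericMatrix W, NumericMatrix Trans) {
  const int N = feats.size(), L = W.ncol();
  if (labels.size() != N) stop("length mismatch");
  double s = 0.0;
  std::vector<double> row(L);
  for (int t = 0; t < N; ++t) {
    int y = labels[t] - 1;
    if (y < 0 || y >= L) stop("label out of range");
    emission_row(feats[t], W, row);
    s += row[y];
    int prev = (t == 0) ? L : labels[t - 1] - 1;
    s += Trans(prev, y);
  }
  return s;
}

// Viterbi; optional additive per-position costs (N x L), e.g. Hamming loss
// for margin-rescaled (loss-augmented) decoding.
// [[Rcpp::export]]
List chain_viterbi(List feats, NumericMatrix W, NumericMatrix Trans,
                   Nullable<NumericMatrix> addcost = R_NilValue) {
  const int N = feats.size(), L = W.ncol();
  if (N == 0) return List::create(_["path"] = IntegerVector(0),
                                  _["score"] = 0.0);
  NumericMatrix cost;
  bool has_cost = addcost.isNotNull();
  if (has_cost) cost = NumericMatrix(addcost);
  std::vector<std::vector<double> > delta(N, std::vector<double>(L));
  std::vector<std::vector<int> > psi(N, std::vector<int>(L, -1));
  std::vector<double> em(L);
  emission_row(feats[0], W, em);
  for (int l = 0; l < L; ++l) {
    delta[0][l] = em[l] + Trans(L, l) + (has_cost ? cost(0, l) : 0.0);
  }
  for (int t = 1; t < N; ++t) {
    emission_row(feats[t], W, em);
    for (int l = 0; l < L; ++l) {
      double best = delta[t - 1][0] + Trans(0, l);
      int arg = 0;
      for (int p = 1; p < L; ++p) {
        double v = delta[t - 1][p] + Trans(p, l);
        if (v > best) { best = v; arg = p; }
      }
      delta[t][l] = best + em[l] + (has_cost ? cost(t, l) : 0.0);
      psi[t][l] = arg;
    }
  }
  double best = delta[N - 1][0];
  int arg = 0;
  for (int l = 1; l < L; ++l) {
    if (delta[N - 1][l] > best) { best = delta[N - 1][l]; arg = l; }
  }
  IntegerVector path(N);
  path[N - 1] = arg + 1;
  for (int t = N - 1; t > 0; --t) {
    arg = psi[t][arg];
    path[t - 1] = arg + 1;
  }
  return List::create(_["path"] = path, _["score"] = best);
}

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// Forward-backward in log space: log-partition, node marginals, and
// optionally pairwise marginals (list of L x L matrices for t = 2..N).
// [[Rcpp::export]]
List chain_forward_backward(List feats, NumericMatrix W, NumericMatrix Trans,
                            bool pairwise = false) {
  const int N = feats.size(), L = W.ncol();
  if (N == 0) {
    return List::create(_["log_partition"] = 0.0,
                        _["marginals"] = NumericMatrix(0, L));
  }
  NumericMatrix E = chain_emissions(feats, W);
  NumericMatrix alpha(N, L), beta(N, L);
  std::vector<double> tmp(L);
  for (int l = 0; l < L; ++l) alpha(0, l) = Trans(L, l) + E(0, l);
  for (int t = 1; t < N; ++t) {
    for (int l = 0; l < L; ++l) {
      for (int p = 0; p < L; ++p) tmp[p] = alpha(t - 1, p) + Trans(p, l);
      alpha(t, l) = logsumexp(tmp) + E(t, l);
    }
  }
  for (int l = 0; l < L; ++l) beta(N - 1, l) = 0.0;
  for (int t = N - 2; t >= 0; --t) {
    for (int l = 0; l < L; ++l) {
      for (int q = 0; q < L; ++q) {
        tmp[q] = Trans(l, q) + E(t + 1, q) + beta(t + 1, q);
      }
      beta(t, l) = logsumexp(tmp);
    }
  }
  for (int l = 0; l < L; ++l) tmp[l] = alpha(N - 1, l);
  double logZ = logsumexp(tmp);
  NumericMatrix marg(N, L);
  for (int t = 0; t < N; ++t) {
    for (int l = 0; l < L; ++l) {
      marg(t, l) = std::exp(alpha(t, l) + beta(t, l) - logZ);
    }
  }
  List out = List::create(_["log_partition"] = logZ, _["marginals"] = marg);
  if (pairwise) {
    List pm(N >= 2 ? N - 1 : 0);
    for (int t = 1; t < N; ++t) {
      NumericMatrix P(L, L);
      for (int a = 0; a < L; ++a) {
        for (int b = 0; b < L; ++b) {
          P(a, b) = std::exp(alpha(t - 1, a) + Trans(a, b) + E(t, b) +
                             beta(t, b) - logZ);
        }
      }
      pm[t - 1] = P;
    }
    out["pairwise"] = pm;
  }
  return out;
}

// Negative conditional log-likelihood with L2 penalty, plus its gradient,
// summed over a dataset. dataset: List of List(feats=<List>, labels=<int>).
// [[Rcpp::export]]
List crf_negloglik_grad(List dataset, NumericMatrix W, NumericMatrix Trans,
                        double l2) {
  const int L = W.ncol(), nfeat = W.nrow();
  NumericMatrix gW(nfeat, L), gT(L + 1, L);
  double nll = 0.0;
  std::vector<double> tmp(L);
  for (int s = 0; s < dataset.size(); ++s) {
    List inst = dataset[s];
    List feats = inst["feats"];
    IntegerVector labels = inst["labels"];
    const int N = feats.size();
    if (N == 0) continue;
    NumericMatrix E = chain_emissions(feats, W);
    // forward / backward
    NumericMatrix alpha(N, L), beta(N, L);
    for (int l = 0; l < L; ++l) alpha(0, l) = Trans(L, l) + E(0, l);
    for (int t = 1; t < N; ++t) {
      for (int l = 0; l < L; ++l) {
        for (int p = 0; p < L; ++p) tmp[p] = alpha(t - 1, p) + Trans(p, l);
        alpha(t, l) = logsumexp(tmp) + E(t, l);
      }
    }
    for (int l = 0; l < L; ++l) beta(N - 1, l) = 0.0;
    for (int t = N - 2; t >= 0; --t) {
      for (int l = 0; l < L; ++l) {
        for (int q = 0; q < L; ++q) {
          tmp[q] = Trans(l, q) + E(t + 1, q) + beta(t + 1, q);
        }
        beta(t, l) = logsumexp(tmp);
      }
    }
    for (int l = 0; l < L; ++l) tmp[l] = alpha(N - 1, l);
    double logZ = logsumexp(tmp);
    // gold score and empirical counts
    double gold = 0.0;
    for (int t = 0; t < N; ++t) {
      int y = labels[t] - 1;
      gold += E(t, y);
      int prev = (t == 0) ? L : labels[t - 1] - 1;
      gold += Trans(prev, y);
      IntegerVector f = feats[t];
      for (int k = 0; k < f.size(); ++k) {
        int id = f[k] - 1;
        if (id >= 0 && id < nfeat) gW(id, y) -= 1.0;
      }
      gT(prev, y) -= 1.0;
    }
    nll += logZ - gold;
    // expected counts
    for (int t = 0; t < N; ++t) {
      IntegerVector f = feats[t];
      for (int l = 0; l < L; ++l) {
        double m = std::exp(alpha(t, l) + beta(t, l) - logZ);
        for (int k = 0; k < f.size(); ++k) {
          int id = f[k] - 1;
          if (id >= 0 && id < nfeat) gW(id, l) += m;
        }
        if (t == 0) gT(L, l) += m;
      }
      if (t >= 1) {
        for (int a = 0; a < L; ++a) {
          for (int b = 0; b < L; ++b) {
            gT(a, b) += std::exp(alpha(t - 1, a) + Trans(a, b) + E(t, b) +
                                 beta(t, b) - logZ);
          }
        }
      }
    }
  }
  // L2 penalty
  double pen = 0.0;
  for (int j = 0; j < nfeat; ++j) {
    for (int l = 0; l < L; ++l) {
      pen += W(j, l) * W(j, l);
      gW(j, l) += l2 * W(j, l);
    }
  }
  for (int a = 0; a <= L; ++a) {
    for (int b = 0; b < L; ++b) {
      pen += Trans(a, b) * Trans(a, b);
      gT(a, b) += l2 * Trans(a, b);
    }
  }
  nll += 0.5 * l2 * pen;
  return List::create(_["value"] = nll, _["grad_W"] = gW, _["grad_T"] = gT);
}

// SMO-style dual coordinate ascent for the cutting-plane working-set QP:
//   max_a  sum_j a_j * delta_j - 0.5 * a' K a
//   s.t.   a_j >= 0,  sum_{j : ex_j = i} a_j <= cap_i  for every example i.
// K is the Gram matrix of constraint difference-vectors. Convergence when the
// maximal KKT violation of the box/simplex conditions drops below tol (same
// units as the cutting-plane epsilon: dual-objective gradient).
// [[Rcpp::export]]
NumericVector qp_dual_ascent(NumericMatrix K, NumericVector delta,
                             IntegerVector ex, NumericVector cap,
                             NumericVector alpha0, double tol = 1e-6,
                             int max_sweeps = 500) {
  const int n = delta.size();
  NumericVector alpha = clone(alpha0);
  int n_ex = cap.size();
  std::vector<double> exsum(n_ex, 0.0);
  for (int j = 0; j < n; ++j) exsum[ex[j] - 1] += alpha[j];
  // g = delta - K alpha
  std::vector<double> g(n);
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    for (int k = 0; k < n; ++k) s += K(j, k) * alpha[k];
    g[j] = delta[j] - s;
  }
  // One coordinate update; returns the step taken.
  auto update = [&](int j) -> double {
    double kjj = K(j, j);
    int i = ex[j] - 1;
    double lo = -alpha[j];
    double hi = cap[i] - exsum[i];
    double d;
    if (kjj > 1e-14) {
      d = g[j] / kjj;
    } else {
      // zero-curvature direction: move to whichever bound helps
      d = (g[j] > 0) ? hi : lo;
    }
    if (d > hi) d = hi;
    if (d < lo) d = lo;
    if (std::fabs(d) < 1e-15) return 0.0;
    alpha[j] += d;
    exsum[i] += d;
    for (int k = 0; k < n; ++k) g[k] -= d * K(k, j);
    return d;
  };
  // Pairwise transfer within one example: when the example's budget is
  // exhausted, single-coordinate moves stall; move mass from the
  // lowest-gradient support constraint to the highest-gradient one along
  // e_k - e_j (the SMO direction that keeps the budget fixed).
  auto transfer = [&](int j, int k) -> double {
    double grad = g[k] - g[j];
    double curv = K(k, k) - 2.0 * K(j, k) + K(j, j);
    double t;
    if (curv > 1e-14) t = grad / curv;
    else t = (grad > 0) ? alpha[j] : -alpha[k];
    if (t > alpha[j]) t = alpha[j];
    if (t < -alpha[k]) t = -alpha[k];
    if (std::fabs(t) < 1e-15) return 0.0;
    alpha[j] -= t;
    alpha[k] += t;
    for (int q = 0; q < n; ++q) g[q] -= t * (K(q, k) - K(q, j));
    return t;
  };
  // group constraint indices by example
  std::vector<std::vector<int> > by_ex(n_ex);
  for (int j = 0; j < n; ++j) by_ex[ex[j] - 1].push_back(j);
  auto transfer_pass = [&]() {
    for (int i = 0; i < n_ex; ++i) {
      if ((cap[i] - exsum[i]) > 1e-12) continue; // budget slack: no need
      const std::vector<int>& js = by_ex[i];
      if (js.size() < 2) continue;
      for (int it = 0; it < 20; ++it) {
        int jmin = -1, kmax = -1;
        double gmin = 0.0, gmax = 0.0;
        for (size_t s = 0; s < js.size(); ++s) {
          int j = js[s];
          if (alpha[j] > 1e-12 && (jmin < 0 || g[j] < gmin)) {
            jmin = j; gmin = g[j];
          }
          if (kmax < 0 || g[j] > gmax) { kmax = j; gmax = g[j]; }
        }
        if (jmin < 0 || kmax < 0 || jmin == kmax) break;
        if (gmax - gmin < 1e-14) break;
        if (transfer(jmin, kmax) == 0.0) break;
      }
    }
  };
  // KKT violation over a coordinate set (including the transfer direction
  // for budget-tight examples).
  auto kkt_over = [&](const std::vector<int>& set) -> double {
    double kkt = 0.0;
    for (size_t s = 0; s < set.size(); ++s) {
      int j = set[s];
      int i = ex[j] - 1;
      bool room_up = (cap[i] - exsum[i]) > 1e-12;
      if (room_up && g[j] > kkt) kkt = g[j];
      if (alpha[j] > 1e-12 && -g[j] > kkt) kkt = -g[j];
    }
    for (int i = 0; i < n_ex; ++i) {
      if ((cap[i] - exsum[i]) > 1e-12) continue;
      const std::vector<int>& js = by_ex[i];
      double gmin = R_PosInf, gmax = R_NegInf;
      for (size_t s = 0; s < js.size(); ++s) {
        int j = js[s];
        if (alpha[j] > 1e-12 && g[j] < gmin) gmin = g[j];
        if (g[j] > gmax) gmax = g[j];
      }
      if (std::isfinite(gmin) && std::isfinite(gmax) && gmax - gmin > kkt) {
        kkt = gmax - gmin;
      }
    }
    return kkt;
  };
  std::vector<int> all(n);
  for (int j = 0; j < n; ++j) all[j] = j;
  // Active-set strategy: optimize over the support (alpha > 0) between full
  // sweeps; converged when a full sweep leaves no KKT violation above tol.
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    for (int j = 0; j < n; ++j) update(j); // full sweep
    transfer_pass();
    std::vector<int> active;
    for (int j = 0; j < n; ++j) if (alpha[j] > 1e-12) active.push_back(j);
    for (int inner = 0; inner < 50; ++inner) {
      for (size_t s = 0; s < active.size(); ++s) update(active[s]);
      transfer_pass();
      if (kkt_over(active) < tol) break;
    }
    if (kkt_over(all) < tol) break;
  }
  return alpha;
}
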