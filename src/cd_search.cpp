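// Block-cyclic coordinate-descent core for penalized Gaussian DAG
// estimation.  Operates on the sample correlation matrix S of
// column-standardized data; the objective (per-n-normalized) is
//
//   f(B) = sum_j 0.5*(1 + log(2*pi*q_j)) + sum_edges pen(|B_ij|)
//
// with q_j = 1 - 2 B_.j' s_j + B_.j' S B_.j the profiled conditional
// variance, and pen an L1 or MCP(gamma) penalty with multiplier lam_n.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double Q_FLOOR = 1e-12;

struct Problem {
  int p;
  const double* S;       // p x p, column-major
  std::vector<int> allowed;  // p x p, 0/1
  double lam_n, gamma;
  bool mcp;

  double Sat(int i, int j) const { return S[i + j * p]; }
};

struct State {
  std::vector<double> B;  // p x p column-major, B[i + j*p] = coef i -> j
  std::vector<double> q;  // profiled conditional variances
};

static inline double pen_val(const Problem& pb, double t) {
  if (!pb.mcp) return pb.lam_n * t;
  if (t <= pb.gamma * pb.lam_n) return pb.lam_n * t - t * t / (2.0 * pb.gamma);
  return pb.gamma * pb.lam_n * pb.lam_n / 2.0;
}

static inline double pen_deriv(const Problem& pb, double t) {
  if (!pb.mcp) return pb.lam_n;
  double d = pb.lam_n - t / pb.gamma;
  return d > 0.0 ? d : 0.0;
}

static double node_q(const Problem& pb, const State& st, int j) {
  const int p = pb.p;
  const double* bj = &st.B[j * p];
  double lin = 0.0, quad = 0.0;
  for (int i = 0; i < p; ++i) {
    if (bj[i] != 0.0) {
      lin += bj[i] * pb.Sat(i, j);
      double acc = 0.0;
      for (int k = 0; k < p; ++k) {
        if (bj[k] != 0.0) acc += bj[k] * pb.Sat(i, k);
      }
      quad += bj[i] * acc;
    }
  }
  double q = 1.0 - 2.0 * lin + quad;
  return q > Q_FLOOR ? q : Q_FLOOR;
}

static inline double dir_obj(const Problem& pb, double beta, double q0,
                             double b) {
  double q = q0 - 2.0 * b * beta + beta * beta;
  if (q < Q_FLOOR) q = Q_FLOOR;
  return 0.5 * std::log(q) + pen_val(pb, std::fabs(beta));
}

// best coefficient for one direction given partial covariance b and
// rest-variance q0: threshold proposal, Newton polish, exact acceptance
static double best_coef(const Problem& pb, double q0, double b, double old,
                        double* f_out) {
  double cand[5];
  int nc = 0;
  cand[nc++] = 0.0;
  cand[nc++] = b;
  if (old != 0.0) cand[nc++] = old;
  double prop;
  if (!pb.mcp) {
    double t = std::fabs(b) - pb.lam_n * q0;
    prop = t > 0.0 ? (b > 0 ? t : -t) : 0.0;
  } else {
    double denom = 1.0 - q0 / pb.gamma;
    if (std::fabs(b) <= pb.lam_n * q0) prop = 0.0;
    else if (std::fabs(b) <= pb.gamma * pb.lam_n && denom > 1e-8)
      prop = (b > 0 ? 1.0 : -1.0) * (std::fabs(b) - pb.lam_n * q0) / denom;
    else prop = b;
  }
  cand[nc++] = prop;

  double best = cand[0], fbest = dir_obj(pb, cand[0], q0, b);
  for (int k = 1; k < nc; ++k) {
    double f = dir_obj(pb, cand[k], q0, b);
    if (f < fbest) { fbest = f; best = cand[k]; }
  }
  if (best != 0.0) {
    double beta = best;
    double s = beta > 0 ? 1.0 : -1.0;
    for (int it = 0; it < 12; ++it) {
      double q = q0 - 2.0 * b * beta + beta * beta;
      if (q < Q_FLOOR) q = Q_FLOOR;
      double g1 = (beta - b) / q + s * pen_deriv(pb, std::fabs(beta));
      double h = (q - 2.0 * (beta - b) * (beta - b)) / (q * q);
      if (pb.mcp && std::fabs(beta) < pb.gamma * pb.lam_n) h -= 1.0 / pb.gamma;
      if (!std::isfinite(g1) || !std::isfinite(h) || h <= 1e-10) break;
      double step = g1 / h;
      double beta_new = beta - step;
      if ((beta_new > 0 ? 1.0 : -1.0) != s) beta_new = s * 1e-12;
      if (dir_obj(pb, beta_new, q0, b) > dir_obj(pb, beta, q0, b) - 1e-16)
        break;
      beta = beta_new;
      if (std::fabs(step) < 1e-13) break;
    }
    double f = dir_obj(pb, beta, q0, b);
    if (f < fbest) { fbest = f; best = beta; }
  }
  *f_out = fbest;
  return best;
}

static double node_f(const Problem& pb, const State& st, int j) {
  const int p = pb.p;
  double f = 0.5 * std::log(st.q[j]);
  const double* bj = &st.B[j * p];
  for (int i = 0; i < p; ++i) {
    if (bj[i] != 0.0) f += pen_val(pb, std::fabs(bj[i]));
  }
  return f;
}

static double total_f(const Problem& pb, const State& st) {
  const int p = pb.p;
  double f = 0.0;
  for (int j = 0; j < p; ++j) {
    f += 0.5 * (1.0 + std::log(2.0 * M_PI * st.q[j]));
    const double* bj = &st.B[j * p];
    for (int i = 0; i < p; ++i) {
      if (bj[i] != 0.0) f += pen_val(pb, std::fabs(bj[i]));
    }
  }
  return f;
}

// DFS: directed path from -> to in the nonzero pattern of B
static bool has_path(const Problem& pb, const State& st, int from, int to) {
  const int p = pb.p;
  if (from == to) return true;
  std::vector<char> seen(p, 0);
  std::vector<int> stack;
  stack.push_back(from);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (v == to) return true;
    if (seen[v]) continue;
    seen[v] = 1;
    for (int w = 0; w < p; ++w) {
      if (st.B[v + w * p] != 0.0 && !seen[w]) stack.push_back(w);
    }
  }
  return false;
}

// coordinate descent on node j's column over `support`; existing
// parents may be thresholded out
static void refit_node(const Problem& pb, State& st, int j,
                       const std::vector<int>& support) {
  const int p = pb.p;
  if (support.empty()) { st.q[j] = node_q(pb, st, j); return; }
  for (int pass = 0; pass < 50; ++pass) {
    double delta = 0.0;
    for (size_t k = 0; k < support.size(); ++k) {
      int i = support[k];
      double old = st.B[i + j * p];
      st.B[i + j * p] = 0.0;
      double q0 = node_q(pb, st, j);
      double b = pb.Sat(i, j);
      const double* bj = &st.B[j * p];
      for (int m = 0; m < p; ++m) {
        if (bj[m] != 0.0) b -= bj[m] * pb.Sat(m, i);
      }
      double fdummy;
      double beta = best_coef(pb, q0, b, old, &fdummy);
      st.B[i + j * p] = beta;
      double d = std::fabs(beta - old);
      if (d > delta) delta = d;
    }
    if (delta < 1e-10) break;
  }
  st.q[j] = node_q(pb, st, j);
}

static std::vector<int> col_support(const Problem& pb, const State& st,
                                    int j) {
  std::vector<int> out;
  for (int i = 0; i < pb.p; ++i) {
    if (st.B[i + j * pb.p] != 0.0) out.push_back(i);
  }
  return out;
}

// joint update of the (i, j) block: {no edge, i->j, j->i}, re-optimizing
// both full columns per option; keeps the pre-update configuration if no
// option improves (monotone descent).  Ties between directions go to
// i -> j (the lower (parent, child) order).
static double pair_update(const Problem& pb, State& st, int i, int j) {
  const int p = pb.p;
  std::vector<double> Bi_orig(p), Bj_orig(p);
  for (int k = 0; k < p; ++k) {
    Bi_orig[k] = st.B[k + i * p];
    Bj_orig[k] = st.B[k + j * p];
  }
  double qi_orig = st.q[i], qj_orig = st.q[j];
  double f_orig = node_f(pb, st, i) + node_f(pb, st, j);

  st.B[i + j * p] = 0.0;
  st.B[j + i * p] = 0.0;
  std::vector<int> sup_i = col_support(pb, st, i);
  std::vector<int> sup_j = col_support(pb, st, j);
  bool can_ij = pb.allowed[i + j * p] && !has_path(pb, st, j, i);
  bool can_ji = pb.allowed[j + i * p] && !has_path(pb, st, i, j);

  struct Opt { double f; std::vector<double> Bi, Bj; double qi, qj; };
  Opt best;
  best.f = f_orig; best.Bi = Bi_orig; best.Bj = Bj_orig;
  best.qi = qi_orig; best.qj = qj_orig;

  auto snapshot = [&](Opt& o) {
    o.Bi.assign(st.B.begin() + i * p, st.B.begin() + (i + 1) * p);
    o.Bj.assign(st.B.begin() + j * p, st.B.begin() + (j + 1) * p);
    o.qi = st.q[i]; o.qj = st.q[j];
    o.f = node_f(pb, st, i) + node_f(pb, st, j);
  };
  auto restore = [&](const Opt& o) {
    std::copy(o.Bi.begin(), o.Bi.end(), st.B.begin() + i * p);
    std::copy(o.Bj.begin(), o.Bj.end(), st.B.begin() + j * p);
    st.q[i] = o.qi; st.q[j] = o.qj;
  };

  refit_node(pb, st, i, sup_i);
  refit_node(pb, st, j, sup_j);
  Opt base;
  snapshot(base);
  if (base.f < best.f - 1e-14) best = base;

  if (can_ij) {
    restore(base);
    std::vector<int> sj = sup_j;
    sj.push_back(i);
    refit_node(pb, st, i, sup_i);
    refit_node(pb, st, j, sj);
    Opt o;
    snapshot(o);
    if (o.f < best.f - 1e-14) best = o;
  }
  if (can_ji) {
    restore(base);
    std::vector<int> si = sup_i;
    si.push_back(j);
    refit_node(pb, st, i, si);
    refit_node(pb, st, j, sup_j);
    Opt o;
    snapshot(o);
    if (o.f < best.f - 1e-14) best = o;
  }
  restore(best);
  double mc = 0.0;
  for (int k = 0; k < p; ++k) {
    mc = std::max(mc, std::fabs(best.Bi[k] - Bi_orig[k]));
    mc = std::max(mc, std::fabs(best.Bj[k] - Bj_orig[k]));
  }
  return mc;
}

static bool run_sweeps(const Problem& pb, State& st, int budget, double tol,
                       std::vector<double>* trace) {
  const int p = pb.p;
  for (int sweep = 0; sweep < budget; ++sweep) {
    double max_change = 0.0;
    for (int i = 0; i < p - 1; ++i) {
      for (int j = i + 1; j < p; ++j) {
        max_change = std::max(max_change, pair_update(pb, st, i, j));
      }
    }
    if (trace) trace->push_back(total_f(pb, st));
    if (max_change < tol) return true;
  }
  return false;
}

// trial-reverse each current edge (old direction tabu), reconverge under
// a small sweep budget, keep on exact improvement
static bool try_reversals(Problem& pb, State& st, double tol) {
  const int p = pb.p;
  std::vector<std::pair<int, int> > edges;
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < p; ++i) {
      if (st.B[i + j * p] != 0.0) edges.push_back(std::make_pair(i, j));
    }
  }
  std::sort(edges.begin(), edges.end());
  for (size_t e = 0; e < edges.size(); ++e) {
    int u = edges[e].first, v = edges[e].second;
    if (st.B[u + v * p] == 0.0 || !pb.allowed[v + u * p]) continue;
    State save = st;
    double f_save = total_f(pb, st);
    st.B[u + v * p] = 0.0;
    if (has_path(pb, st, u, v)) { st = save; continue; }
    refit_node(pb, st, v, col_support(pb, st, v));
    std::vector<int> su = col_support(pb, st, u);
    su.push_back(v);
    refit_node(pb, st, u, su);
    pb.allowed[u + v * p] = 0;
    bool ok = run_sweeps(pb, st, 10, tol, 0);
    pb.allowed[u + v * p] = 1;
    if (ok && total_f(pb, st) < f_save - 1e-10) return true;
    st = save;
  }
  return false;
}

// [[Rcpp::export(name = ".cd_search_cpp")]]
List cd_search_cpp(NumericMatrix S, LogicalMatrix allowed, NumericMatrix B0,
                   double lam_n, std::string penalty, double gamma,
                   int max_iter, double tol, bool refine, bool debug) {
  const int p = S.ncol();
  Problem pb;
  pb.p = p;
  pb.S = S.begin();
  pb.allowed.assign(p * p, 0);
  for (int k = 0; k < p * p; ++k) pb.allowed[k] = allowed[k] ? 1 : 0;
  pb.lam_n = lam_n;
  pb.gamma = gamma;
  pb.mcp = (penalty == "mcp");

  State st;
  st.B.assign(B0.begin(), B0.end());
  st.q.resize(p);
  for (int j = 0; j < p; ++j) st.q[j] = node_q(pb, st, j);

  std::vector<double> trace;
  if (debug) trace.push_back(total_f(pb, st));
  bool converged = run_sweeps(pb, st, max_iter, tol, debug ? &trace : 0);
  if (converged && refine) {
    for (int round = 0; round < 2 * p; ++round) {
      if (!try_reversals(pb, st, tol)) break;
      converged = run_sweeps(pb, st, max_iter, tol, debug ? &trace : 0);
      if (!converged) break;
    }
  }

  NumericMatrix Bout(p, p);
  std::copy(st.B.begin(), st.B.end(), Bout.begin());
  List out = List::create(
    Named("B") = Bout,
    Named("q") = NumericVector(st.q.begin(), st.q.end()),
    Named("f") = total_f(pb, st),
    Named("converged") = converged);
  if (debug) out["trace"] = NumericVector(trace.begin(), trace.end());
  return out;
}
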