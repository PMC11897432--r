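// Core numerics for CNA-tree inference: genotype derivation, validity,
// attachment-table traversal, tree scores, and the Metropolis-Hastings chain
// over (tree, events, nu).
//
// Node labels are 1..n with 0 the root, as in the parent-vector convention.
// Events are stored dense: an n x K matrix of signed per-segment deltas.
// All randomness goes through R's RNG so chains are reproducible via set.seed.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdio>
#include <cstring>
#include <map>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct TreeState {
  int n;                              // nodes excluding root
  int K;                              // segments
  std::vector<int> parent;            // size n; parent[i] is parent label of node i+1, in 0..n
  std::vector<std::vector<int> > ev;  // n rows x K deltas
  std::vector<int> rootp;             // K root ploidies
};

// ---------- small utilities ----------

static int unif_index(int k) {
  int j = (int)(R::unif_rand() * k);
  return (j >= k) ? (k - 1) : j;
}

static std::vector<std::vector<int> > children_of(const TreeState &s) {
  std::vector<std::vector<int> > ch(s.n + 1);
  for (int i = 0; i < s.n; ++i) ch[s.parent[i]].push_back(i + 1);
  return ch;
}

// labels in the subtree rooted at node i (1..n), including i
static std::vector<int> subtree_labels(const TreeState &s, int i) {
  std::vector<std::vector<int> > ch = children_of(s);
  std::vector<int> out, stack;
  stack.push_back(i);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    out.push_back(u);
    for (size_t j = 0; j < ch[u].size(); ++j) stack.push_back(ch[u][j]);
  }
  return out;
}

// genotypes: (n+1) x K, row 0 = root ploidy; parents accumulate into children
static std::vector<std::vector<int> > genotypes_of(const TreeState &s) {
  std::vector<std::vector<int> > gen(s.n + 1, std::vector<int>(s.K, 0));
  for (int k = 0; k < s.K; ++k) gen[0][k] = s.rootp[k];
  std::vector<std::vector<int> > ch = children_of(s);
  std::vector<int> stack;
  for (size_t j = 0; j < ch[0].size(); ++j) stack.push_back(ch[0][j]);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    int p = s.parent[u - 1];
    for (int k = 0; k < s.K; ++k) gen[u][k] = gen[p][k] + s.ev[u - 1][k];
    for (size_t j = 0; j < ch[u].size(); ++j) stack.push_back(ch[u][j]);
  }
  return gen;
}

// 0 = valid, 1 = negative_state, 2 = regain_after_zero, 3 = duplicate_genotype
static int validity_code(const TreeState &s, const std::vector<std::vector<int> > &gen) {
  for (int u = 0; u <= s.n; ++u)
    for (int k = 0; k < s.K; ++k)
      if (gen[u][k] < 0) return 1;
  // regain after zero: once a segment hits state 0 at a node, no event below
  // that node may increase it
  std::vector<std::vector<int> > ch = children_of(s);
  std::vector<std::pair<int, std::vector<char> > > stack;
  std::vector<char> rootflag(s.K);
  for (int k = 0; k < s.K; ++k) rootflag[k] = (gen[0][k] == 0);
  stack.push_back(std::make_pair(0, rootflag));
  while (!stack.empty()) {
    int u = stack.back().first;
    std::vector<char> flag = stack.back().second;
    stack.pop_back();
    for (size_t j = 0; j < ch[u].size(); ++j) {
      int c = ch[u][j];
      std::vector<char> f2 = flag;
      for (int k = 0; k < s.K; ++k) {
        if (f2[k] && s.ev[c - 1][k] > 0) return 2;
        if (gen[c][k] == 0) f2[k] = 1;
      }
      stack.push_back(std::make_pair(c, f2));
    }
  }
  std::set<std::vector<int> > seen;
  for (int u = 0; u <= s.n; ++u)
    if (!seen.insert(gen[u]).second) return 3;
  return 0;
}

// event prior for one node's delta row, matching the generative event
// distribution: shifted-Poisson segment count, uniform choice among the
// C(K, k) segment subsets, shifted-Poisson magnitudes, uniform signs. The
// subset factor keeps the prior normalized over events; without it the
// posterior mass diverges towards large trees.
static double event_prior_row(const std::vector<int> &row, double ls, double lc) {
  int k = 0;
  double lp = 0.0;
  for (size_t j = 0; j < row.size(); ++j) {
    if (row[j] != 0) {
      ++k;
      lp += R::dpois(std::abs(row[j]) - 1.0, lc, 1) + std::log(0.5);
    }
  }
  if (k == 0) return NEG_INF;  // empty event: never part of a valid tree
  return lp + R::dpois(k - 1.0, ls, 1) -
         R::lchoose((double)row.size(), (double)k);
}

static double event_prior_total(const TreeState &s, double ls, double lc) {
  double lp = 0.0;
  for (int i = 0; i < s.n; ++i) lp += event_prior_row(s.ev[i], ls, lc);
  return lp;
}

static inline double flo(int c, double eta) { return c > 0 ? (double)c : eta; }

// ---------- likelihood ----------

// per-cell log-likelihoods of all attachments relative to the root, by
// parent-to-child traversal touching only the segments changed by each event
static void attach_table_fill(const TreeState &s,
                              const std::vector<std::vector<int> > &gen,
                              const NumericMatrix &D, const NumericVector &sizes,
                              const std::vector<double> &Nj,
                              double nu, double eta, bool multinomial,
                              std::vector<double> &rel /* m*(n+1), col-major */) {
  int m = D.nrow();
  std::vector<double> Z(s.n + 1, 0.0);
  for (int u = 0; u <= s.n; ++u) {
    double z = 0.0;
    for (int k = 0; k < s.K; ++k) z += flo(gen[u][k], eta) * sizes[k];
    Z[u] = z;
  }
  for (int j = 0; j < m; ++j) rel[j] = 0.0;  // root column
  std::vector<std::vector<int> > ch = children_of(s);
  std::vector<int> stack;
  for (size_t j = 0; j < ch[0].size(); ++j) stack.push_back(ch[0][j]);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    int p = s.parent[u - 1];
    const double *pc = &rel[(size_t)p * m];
    double *uc = &rel[(size_t)u * m];
    if (multinomial) {
      double dlZ = std::log(Z[u]) - std::log(Z[p]);
      for (int j = 0; j < m; ++j) uc[j] = pc[j] - Nj[j] * dlZ;
      for (int k = 0; k < s.K; ++k) {
        if (s.ev[u - 1][k] == 0) continue;
        double dl = std::log(flo(gen[u][k], eta)) - std::log(flo(gen[p][k], eta));
        for (int j = 0; j < m; ++j) uc[j] += D(j, k) * dl;
      }
    } else {
      // Z-dependent Gamma terms plus the changed product terms
      double cst = std::lgamma(nu * Z[u]) - std::lgamma(nu * Z[p]);
      for (int k = 0; k < s.K; ++k) {
        if (s.ev[u - 1][k] == 0) continue;
        double au = nu * flo(gen[u][k], eta) * sizes[k];
        double ap = nu * flo(gen[p][k], eta) * sizes[k];
        cst += std::lgamma(ap) - std::lgamma(au);
      }
      for (int j = 0; j < m; ++j) {
        double v = pc[j] + cst;
        v -= std::lgamma(Nj[j] + nu * Z[u]) - std::lgamma(Nj[j] + nu * Z[p]);
        uc[j] = v;
      }
      for (int k = 0; k < s.K; ++k) {
        if (s.ev[u - 1][k] == 0) continue;
        double au = nu * flo(gen[u][k], eta) * sizes[k];
        double ap = nu * flo(gen[p][k], eta) * sizes[k];
        for (int j = 0; j < m; ++j)
          uc[j] += std::lgamma(D(j, k) + au) - std::lgamma(D(j, k) + ap);
      }
    }
    for (size_t j = 0; j < ch[u].size(); ++j) stack.push_back(ch[u][j]);
  }
}

// absolute log-likelihood of each cell attached at the root
static std::vector<double> root_loglik_vec(const std::vector<int> &rootp,
                                           const NumericMatrix &D,
                                           const NumericVector &sizes,
                                           const std::vector<double> &Nj,
                                           double nu, double eta, bool multinomial) {
  int m = D.nrow(), K = D.ncol();
  std::vector<double> out(m, 0.0);
  double Z0 = 0.0;
  for (int k = 0; k < K; ++k) Z0 += flo(rootp[k], eta) * sizes[k];
  if (multinomial) {
    double lZ0 = std::log(Z0);
    for (int j = 0; j < m; ++j) out[j] = -Nj[j] * lZ0;
    for (int k = 0; k < K; ++k) {
      double dl = std::log(flo(rootp[k], eta) * sizes[k]);
      for (int j = 0; j < m; ++j) out[j] += D(j, k) * dl;
    }
  } else {
    double lgZ = std::lgamma(nu * Z0);
    for (int j = 0; j < m; ++j) out[j] = lgZ - std::lgamma(Nj[j] + nu * Z0);
    for (int k = 0; k < K; ++k) {
      double a = nu * flo(rootp[k], eta) * sizes[k];
      double lga = std::lgamma(a);
      for (int j = 0; j < m; ++j) out[j] += std::lgamma(D(j, k) + a) - lga;
    }
  }
  return out;
}

// ---------- fast workspace scorer ----------

// Reusable buffers so per-proposal scoring does not allocate.
struct Workspace {
  std::vector<int> head, nxt;     // children linked lists over labels 0..n
  std::vector<int> order;         // root-to-leaf topological order of 1..n
  std::vector<int> gen;           // (n+1) x K flat genotypes, row-major
  std::vector<double> Z;          // per-node eta-floored normalizers
  std::vector<double> rel;        // m x (n+1) relative log-likelihoods, col-major
  std::vector<int> sortidx;       // row indices for the duplicate check
};

// genotypes + topological order; returns false on a malformed parent vector
static bool ws_genotypes(const TreeState &s, Workspace &ws) {
  int n = s.n, K = s.K;
  ws.head.assign(n + 1, -1);
  ws.nxt.assign(n + 1, -1);
  for (int i = n; i >= 1; --i) {  // prepend so traversal is label-ascending
    int p = s.parent[i - 1];
    ws.nxt[i] = ws.head[p];
    ws.head[p] = i;
  }
  ws.order.clear();
  ws.gen.resize((size_t)(n + 1) * K);
  for (int k = 0; k < K; ++k) ws.gen[k] = s.rootp[k];
  // iterative DFS from the root
  static thread_local std::vector<int> stack;
  stack.clear();
  for (int c = ws.head[0]; c != -1; c = ws.nxt[c]) stack.push_back(c);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    ws.order.push_back(u);
    int p = s.parent[u - 1];
    const int *gp = &ws.gen[(size_t)p * K];
    int *gu = &ws.gen[(size_t)u * K];
    const std::vector<int> &ev = s.ev[u - 1];
    for (int k = 0; k < K; ++k) gu[k] = gp[k] + ev[k];
    for (int c = ws.head[u]; c != -1; c = ws.nxt[c]) stack.push_back(c);
  }
  return (int)ws.order.size() == n;
}

// validity on the workspace genotypes; same codes as validity_code
static int ws_validity(const TreeState &s, Workspace &ws) {
  int n = s.n, K = s.K;
  bool any_zero = false;
  for (size_t j = 0; j < ws.gen.size(); ++j) {
    if (ws.gen[j] < 0) return 1;
    if (ws.gen[j] == 0) any_zero = true;
  }
  if (any_zero) {
    // regain check only needed when some state actually hits zero
    static thread_local std::vector<char> flags;
    static thread_local std::vector<char> nodeflags;
    nodeflags.assign((size_t)(n + 1) * K, 0);
    for (int k = 0; k < K; ++k)
      if (ws.gen[k] == 0) nodeflags[k] = 1;
    for (size_t oi = 0; oi < ws.order.size(); ++oi) {
      int u = ws.order[oi];
      int p = s.parent[u - 1];
      const char *fp = &nodeflags[(size_t)p * K];
      char *fu = &nodeflags[(size_t)u * K];
      const int *gu = &ws.gen[(size_t)u * K];
      const std::vector<int> &ev = s.ev[u - 1];
      for (int k = 0; k < K; ++k) {
        if (fp[k] && ev[k] > 0) return 2;
        fu[k] = fp[k] || (gu[k] == 0);
      }
    }
  }
  // duplicate genotypes via index sort over the flat rows
  ws.sortidx.resize(n + 1);
  for (int u = 0; u <= n; ++u) ws.sortidx[u] = u;
  const int *g = ws.gen.data();
  std::sort(ws.sortidx.begin(), ws.sortidx.end(), [g, K](int a, int b) {
    const int *ra = g + (size_t)a * K, *rb = g + (size_t)b * K;
    for (int k = 0; k < K; ++k)
      if (ra[k] != rb[k]) return ra[k] < rb[k];
    return false;
  });
  for (int u = 0; u < n; ++u) {
    const int *ra = g + (size_t)ws.sortidx[u] * K;
    const int *rb = g + (size_t)ws.sortidx[u + 1] * K;
    bool same = true;
    for (int k = 0; k < K; ++k)
      if (ra[k] != rb[k]) { same = false; break; }
    if (same) return 3;
  }
  return 0;
}

// attachment table on workspace buffers (raw column-major D access)
static void ws_attach_table(const TreeState &s, Workspace &ws, const double *Dp,
                            int m, const double *sz, const std::vector<double> &Nj,
                            double nu, double eta, bool multinomial) {
  int n = s.n, K = s.K;
  ws.Z.assign(n + 1, 0.0);
  for (int u = 0; u <= n; ++u) {
    const int *gu = &ws.gen[(size_t)u * K];
    double z = 0.0;
    for (int k = 0; k < K; ++k) z += flo(gu[k], eta) * sz[k];
    ws.Z[u] = z;
  }
  ws.rel.assign((size_t)m * (n + 1), 0.0);
  for (size_t oi = 0; oi < ws.order.size(); ++oi) {
    int u = ws.order[oi];
    int p = s.parent[u - 1];
    const double *pc = &ws.rel[(size_t)p * m];
    double *uc = &ws.rel[(size_t)u * m];
    const int *gu = &ws.gen[(size_t)u * K];
    const int *gp = &ws.gen[(size_t)p * K];
    const std::vector<int> &ev = s.ev[u - 1];
    if (multinomial) {
      double dlZ = std::log(ws.Z[u]) - std::log(ws.Z[p]);
      for (int j = 0; j < m; ++j) uc[j] = pc[j] - Nj[j] * dlZ;
      for (int k = 0; k < K; ++k) {
        if (ev[k] == 0) continue;
        double dl = std::log(flo(gu[k], eta)) - std::log(flo(gp[k], eta));
        const double *dk = Dp + (size_t)k * m;
        for (int j = 0; j < m; ++j) uc[j] += dk[j] * dl;
      }
    } else {
      double cst = std::lgamma(nu * ws.Z[u]) - std::lgamma(nu * ws.Z[p]);
      for (int k = 0; k < K; ++k) {
        if (ev[k] == 0) continue;
        cst += std::lgamma(nu * flo(gp[k], eta) * sz[k]) -
               std::lgamma(nu * flo(gu[k], eta) * sz[k]);
      }
      for (int j = 0; j < m; ++j)
        uc[j] = pc[j] + cst -
                (std::lgamma(Nj[j] + nu * ws.Z[u]) - std::lgamma(Nj[j] + nu * ws.Z[p]));
      for (int k = 0; k < K; ++k) {
        if (ev[k] == 0) continue;
        double au = nu * flo(gu[k], eta) * sz[k];
        double ap = nu * flo(gp[k], eta) * sz[k];
        const double *dk = Dp + (size_t)k * m;
        for (int j = 0; j < m; ++j)
          uc[j] += std::lgamma(dk[j] + au) - std::lgamma(dk[j] + ap);
      }
    }
  }
}

static double tree_score_ws(const TreeState &s, Workspace &ws, const double *Dp,
                            int m, const double *sz, const double *w,
                            const std::vector<double> &rootvec,
                            const std::vector<double> &Nj, double nu, double eta,
                            bool multinomial, bool score_max, double ls, double lc,
                            double kappa, double M) {
  if (!ws_genotypes(s, ws)) return NEG_INF;
  if (ws_validity(s, ws) != 0) return NEG_INF;
  ws_attach_table(s, ws, Dp, m, sz, Nj, nu, eta, multinomial);
  int n = s.n;
  double total = event_prior_total(s, ls, lc);
  double attach = 0.0;
  if (score_max) {
    total += -(n - 1.0) * std::log(n + 1.0);
    for (int j = 0; j < m; ++j) {
      double best = 0.0;
      for (int u = 0; u <= n; ++u) {
        double v = ws.rel[(size_t)u * m + j];
        if (v > best) best = v;
      }
      attach += w[j] * (rootvec[j] + best);
    }
  } else {
    total += -kappa * n - (n - 1.0 + M) * std::log(n + 1.0);
    for (int j = 0; j < m; ++j) {
      double best = 0.0;
      for (int u = 0; u <= n; ++u) {
        double v = ws.rel[(size_t)u * m + j];
        if (v > best) best = v;
      }
      double acc = 0.0;
      for (int u = 0; u <= n; ++u) acc += std::exp(ws.rel[(size_t)u * m + j] - best);
      attach += w[j] * (rootvec[j] + best + std::log(acc));
    }
  }
  return total + attach;
}

// ---------- structural edits with label bookkeeping ----------

// insert a new node at label L (1..n+1): existing labels >= L shift up by one
static TreeState insert_node(const TreeState &s, int L, int parentOld,
                             const std::vector<int> &evrow,
                             const std::vector<int> &adoptOld /* labels re-parented to the new node */) {
  TreeState t;
  t.n = s.n + 1; t.K = s.K; t.rootp = s.rootp;
  t.parent.assign(t.n, 0);
  t.ev.assign(t.n, std::vector<int>(t.K, 0));
  std::vector<char> adopted(s.n + 1, 0);
  for (size_t j = 0; j < adoptOld.size(); ++j) adopted[adoptOld[j]] = 1;
  for (int i = 1; i <= s.n; ++i) {
    int newlab = i >= L ? i + 1 : i;
    int p = adopted[i] ? -1 : s.parent[i - 1];  // -1: becomes child of the new node
    int pn;
    if (p == -1) pn = L;
    else pn = (p >= L) ? p + 1 : p;
    t.parent[newlab - 1] = pn;
    t.ev[newlab - 1] = s.ev[i - 1];
  }
  int pn = (parentOld >= L) ? parentOld + 1 : parentOld;
  t.parent[L - 1] = pn;
  t.ev[L - 1] = evrow;
  return t;
}

// delete node i; its children re-parent to its parent; labels > i shift down
static TreeState delete_node(const TreeState &s, int i) {
  TreeState t;
  t.n = s.n - 1; t.K = s.K; t.rootp = s.rootp;
  t.parent.assign(t.n, 0);
  t.ev.assign(t.n, std::vector<int>(t.K, 0));
  int ip = s.parent[i - 1];
  for (int u = 1; u <= s.n; ++u) {
    if (u == i) continue;
    int newlab = u > i ? u - 1 : u;
    int p = s.parent[u - 1];
    if (p == i) p = ip;
    int pn = p > i ? p - 1 : p;
    t.parent[newlab - 1] = pn;
    t.ev[newlab - 1] = s.ev[u - 1];
  }
  return t;
}

// log proposal density of drawing an event row from the generative event
// distribution (shifted-Poisson count, uniform segment subset, shifted-Poisson
// magnitudes, uniform signs)
static double event_draw_logq(const std::vector<int> &row, double ls, double lc, int K) {
  int k = 0;
  double lq = 0.0;
  for (int j = 0; j < K; ++j) {
    if (row[j] != 0) {
      ++k;
      lq += R::dpois(std::abs(row[j]) - 1.0, lc, 1) + std::log(0.5);
    }
  }
  lq += R::dpois(k - 1.0, ls, 1) - R::lchoose((double)K, (double)k);
  return lq;
}

// draw an event row; false when the draw is out of bounds (k > K or |d| > cap)
static bool draw_event_row(int K, double ls, double lc, int max_abs_delta,
                           std::vector<int> &row) {
  row.assign(K, 0);
  int k = 1 + (int)R::rpois(ls);
  if (k > K) return false;
  // uniform k-subset by partial Fisher-Yates
  std::vector<int> idx(K);
  for (int j = 0; j < K; ++j) idx[j] = j;
  for (int j = 0; j < k; ++j) {
    int r = j + unif_index(K - j);
    std::swap(idx[j], idx[r]);
  }
  for (int j = 0; j < k; ++j) {
    int mag = 1 + (int)R::rpois(lc);
    if (mag > max_abs_delta) return false;
    row[idx[j]] = (R::unif_rand() < 0.5) ? mag : -mag;
  }
  return true;
}

// ---------- genotype-preserving prune & reattach ----------

// Enumerate all (node, target) reattachments that keep every node's genotype,
// adjusting the moved node's event row to the genotype difference from its
// new parent. Genotypes, non-negativity and distinctness are all preserved,
// so only the regained-after-zero constraint needs rechecking; it is reduced
// to an O(K) test per candidate using precomputed zero-flags (has any
// ancestor hit state zero per segment) and per-subtree positive-event masks.
// Returns log sum over the neighbourhood of exp(total event prior).
struct GpCand { int node; int target; };

static double gp_neighbourhood(const TreeState &s,
                               const std::vector<std::vector<int> > &gen,
                               double ls, double lc, double base_prior,
                               int max_abs_delta,
                               std::vector<GpCand> *cands,
                               std::vector<double> *logpri) {
  if (cands) cands->clear();
  if (logpri) logpri->clear();
  int n = s.n, K = s.K;
  // children lists and a root-to-leaf order
  std::vector<int> head(n + 1, -1), nxt(n + 1, -1), order;
  for (int i = n; i >= 1; --i) {
    int p = s.parent[i - 1];
    nxt[i] = head[p];
    head[p] = i;
  }
  order.reserve(n);
  {
    std::vector<int> stack;
    for (int c = head[0]; c != -1; c = nxt[c]) stack.push_back(c);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      order.push_back(u);
      for (int c = head[u]; c != -1; c = nxt[c]) stack.push_back(c);
    }
  }
  // zflag[u][k]: u or an ancestor of u has state zero in segment k
  std::vector<char> zflag((size_t)(n + 1) * K, 0);
  for (int k = 0; k < K; ++k) zflag[k] = (gen[0][k] == 0);
  for (size_t oi = 0; oi < order.size(); ++oi) {
    int u = order[oi], p = s.parent[u - 1];
    for (int k = 0; k < K; ++k)
      zflag[(size_t)u * K + k] = zflag[(size_t)p * K + k] || (gen[u][k] == 0);
  }
  // spos[i][k]: any node strictly below i (children and deeper) has a
  // positive event delta on segment k
  std::vector<char> spos((size_t)(n + 1) * K, 0);
  for (size_t oi = order.size(); oi-- > 0;) {
    int u = order[oi], p = s.parent[u - 1];
    char *pp = &spos[(size_t)p * K];
    const char *pu = &spos[(size_t)u * K];
    for (int k = 0; k < K; ++k)
      pp[k] = pp[k] || pu[k] || (s.ev[u - 1][k] > 0);
  }
  // subtree membership per node via an interval over a DFS ordering
  std::vector<int> tin(n + 1, 0), tout(n + 1, 0);
  {
    int clock = 0;
    std::vector<int> stack, phase;
    stack.push_back(0); phase.push_back(0);
    // iterative Euler tour
    std::vector<int> it(n + 1);
    for (int u = 0; u <= n; ++u) it[u] = head[u];
    std::vector<int> st;
    st.push_back(0);
    tin[0] = ++clock;
    while (!st.empty()) {
      int u = st.back();
      if (it[u] != -1) {
        int c = it[u];
        it[u] = nxt[c];
        tin[c] = ++clock;
        st.push_back(c);
      } else {
        tout[u] = clock;
        st.pop_back();
      }
    }
  }
  std::vector<double> lp;
  std::vector<int> newrow(K);
  for (int i = 1; i <= n; ++i) {
    double row_old = event_prior_row(s.ev[i - 1], ls, lc);
    const char *pi = &spos[(size_t)i * K];
    for (int t = 0; t <= n; ++t) {
      if (t == s.parent[i - 1]) continue;
      if (tin[t] >= tin[i] && tin[t] <= tout[i]) continue;  // t inside subtree(i)
      // new event row = genotype difference to the new parent
      bool capped = false;
      int kcnt = 0;
      double rowpri = 0.0;
      const char *zt = &zflag[(size_t)t * K];
      bool invalid = false;
      for (int k = 0; k < K; ++k) {
        int d = gen[i][k] - gen[t][k];
        newrow[k] = d;
        if (std::abs(d) > max_abs_delta) { capped = true; break; }
        if (zt[k] && (d > 0 || pi[k])) { invalid = true; break; }
        if (d != 0) {
          ++kcnt;
          rowpri += R::dpois(std::abs(d) - 1.0, lc, 1) + std::log(0.5);
        }
      }
      if (capped || invalid || kcnt == 0) continue;
      rowpri += R::dpois(kcnt - 1.0, ls, 1) - R::lchoose((double)K, (double)kcnt);
      double pri = base_prior - row_old + rowpri;
      lp.push_back(pri);
      if (cands) {
        GpCand c; c.node = i; c.target = t;
        cands->push_back(c);
      }
      if (logpri) logpri->push_back(pri);
    }
  }
  if (lp.empty()) return NEG_INF;
  double mx = lp[0];
  for (size_t j = 1; j < lp.size(); ++j) if (lp[j] > mx) mx = lp[j];
  double acc = 0.0;
  for (size_t j = 0; j < lp.size(); ++j) acc += std::exp(lp[j] - mx);
  return mx + std::log(acc);
}

// ---------- state serialization for the visit-count audit ----------

static std::string state_key(const TreeState &s) {
  std::string key = "T";
  char buf[16];
  for (int i = 0; i < s.n; ++i) {
    snprintf(buf, sizeof(buf), ",%d", s.parent[i]);
    key += buf;
  }
  key += "|V";
  for (int i = 0; i < s.n; ++i) {
    key += ";";
    for (int k = 0; k < s.K; ++k) {
      snprintf(buf, sizeof(buf), ",%d", s.ev[i][k]);
      key += buf;
    }
  }
  return key;
}

// ---------- conversions ----------

static TreeState state_from_r(const IntegerVector &parent, const IntegerMatrix &events,
                              const IntegerVector &root_ploidy) {
  TreeState s;
  s.n = parent.size();
  s.K = root_ploidy.size();
  s.parent.assign(s.n, 0);
  for (int i = 0; i < s.n; ++i) s.parent[i] = parent[i];
  s.ev.assign(s.n, std::vector<int>(s.K, 0));
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < s.K; ++k) s.ev[i][k] = events(i, k);
  s.rootp.assign(s.K, 0);
  for (int k = 0; k < s.K; ++k) s.rootp[k] = root_ploidy[k];
  return s;
}

static List state_to_r(const TreeState &s) {
  IntegerVector parent(s.n);
  IntegerMatrix events(s.n, s.K);
  IntegerVector rootp(s.K);
  for (int i = 0; i < s.n; ++i) parent[i] = s.parent[i];
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < s.K; ++k) events(i, k) = s.ev[i][k];
  for (int k = 0; k < s.K; ++k) rootp[k] = s.rootp[k];
  return List::create(_["parents"] = parent, _["events"] = events,
                      _["root_ploidy"] = rootp);
}

// ---------- exported: attachment table ----------

// [[Rcpp::export]]
List attachment_table_cpp(IntegerVector parent, IntegerMatrix events,
                          IntegerVector root_ploidy, NumericMatrix D,
                          NumericVector sizes, double nu, double eta,
                          bool multinomial) {
  TreeState s = state_from_r(parent, events, root_ploidy);
  int m = D.nrow();
  std::vector<double> Nj(m, 0.0);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < s.K; ++k) Nj[j] += D(j, k);
  std::vector<std::vector<int> > gen = genotypes_of(s);
  std::vector<double> rel((size_t)m * (s.n + 1));
  attach_table_fill(s, gen, D, sizes, Nj, nu, eta, multinomial, rel);
  NumericMatrix out(m, s.n + 1);
  for (int u = 0; u <= s.n; ++u)
    for (int j = 0; j < m; ++j) out(j, u) = rel[(size_t)u * m + j];
  std::vector<double> rootv = root_loglik_vec(s.rootp, D, sizes, Nj, nu, eta, multinomial);
  return List::create(_["loglik"] = out, _["root_loglik"] = NumericVector(rootv.begin(), rootv.end()));
}

// ---------- exported: MCMC chain ----------

// move order: 1 prune_reattach, 2 label_swap, 3 event_change,
//             4 add_remove_node, 5 condense_split, 6 genotype_preserving, 7 nu_walk
// [[Rcpp::export]]
List run_chain_cpp(IntegerVector parent, IntegerMatrix events, IntegerVector root_ploidy,
                   NumericMatrix D, NumericVector sizes, NumericVector weights,
                   double nu0, double eta, bool multinomial, bool score_max,
                   int iterations, NumericVector move_weights, double nu_sd,
                   double lambda_s, double lambda_c, double kappa,
                   double nu_min, double nu_max, int n_min, int n_max,
                   int max_abs_delta, bool track_states) {
  TreeState cur = state_from_r(parent, events, root_ploidy);
  int m = D.nrow();
  std::vector<double> Nj(m, 0.0);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < cur.K; ++k) Nj[j] += D(j, k);

  double nu = nu0;
  Workspace ws;
  const double *Dp = D.begin();
  const double *szp = sizes.begin();
  const double *wp = weights.begin();
  double M = 0.0;
  for (int j = 0; j < m; ++j) M += weights[j];
  std::vector<double> rootv = root_loglik_vec(cur.rootp, D, sizes, Nj, nu, eta, multinomial);
  double cur_score = tree_score_ws(cur, ws, Dp, m, szp, wp, rootv, Nj, nu, eta,
                                   multinomial, score_max, lambda_s, lambda_c, kappa, M);
  if (!std::isfinite(cur_score)) stop("initial tree is invalid");

  TreeState best = cur;
  double best_nu = nu, best_score = cur_score;
  int best_iter = 0;

  double wsum = 0.0;
  std::vector<double> cumw(7, 0.0);
  for (int j = 0; j < 7; ++j) { wsum += move_weights[j]; cumw[j] = wsum; }
  if (wsum <= 0) stop("all move weights are zero");

  std::vector<int> n_prop(7, 0), n_acc(7, 0);
  std::vector<double> imp_iter, imp_score;
  std::map<std::string, double> visits;

  for (int it = 1; it <= iterations; ++it) {
    double u = R::unif_rand() * wsum;
    int mv = 0;
    while (mv < 6 && u > cumw[mv]) ++mv;
    ++n_prop[mv];

    bool have = false, accepted = false;
    TreeState cand;
    double logHR = 0.0, cand_nu = nu;
    bool nu_changed = false;

    switch (mv) {
      case 0: {  // prune & reattach (labels untouched; HR symmetric)
        if (cur.n < 1) break;
        int i = 1 + unif_index(cur.n);
        std::vector<int> sub = subtree_labels(cur, i);
        std::vector<char> insub(cur.n + 1, 0);
        for (size_t j = 0; j < sub.size(); ++j) insub[sub[j]] = 1;
        std::vector<int> targets;
        for (int t = 0; t <= cur.n; ++t)
          if (!insub[t]) targets.push_back(t);
        if (targets.empty()) break;
        int t = targets[unif_index((int)targets.size())];
        cand = cur;
        cand.parent[i - 1] = t;
        have = true;
        break;
      }
      case 1: {  // label swap: exchange event rows of two distinct nodes
        if (cur.n < 2) break;
        int i = 1 + unif_index(cur.n);
        int j = 1 + unif_index(cur.n - 1);
        if (j >= i) ++j;
        cand = cur;
        std::swap(cand.ev[i - 1], cand.ev[j - 1]);
        have = true;
        break;
      }
      case 2: {  // add/remove one unit of copy-number change at one node
        if (cur.n < 1) break;
        int i = 1 + unif_index(cur.n);
        std::vector<int> nz;
        for (int k = 0; k < cur.K; ++k)
          if (cur.ev[i - 1][k] != 0) nz.push_back(k);
        int r = (int)nz.size();
        if (R::unif_rand() < 0.5) {  // increase magnitude (or create an entry)
          int k = unif_index(cur.K);
          cand = cur;
          int d = cur.ev[i - 1][k];
          if (d == 0) {
            cand.ev[i - 1][k] = (R::unif_rand() < 0.5) ? 1 : -1;
            logHR = std::log(2.0 * cur.K) - std::log(r + 1.0);
          } else {
            int nd = d > 0 ? d + 1 : d - 1;
            if (std::abs(nd) > max_abs_delta) break;
            cand.ev[i - 1][k] = nd;
            logHR = std::log((double)cur.K) - std::log((double)r);
          }
          have = true;
        } else {  // decrease magnitude of an existing entry
          if (r == 0) break;
          int k = nz[unif_index(r)];
          cand = cur;
          int d = cur.ev[i - 1][k];
          int nd = d > 0 ? d - 1 : d + 1;
          cand.ev[i - 1][k] = nd;
          if (nd == 0)
            logHR = std::log((double)r) - std::log(2.0 * cur.K);
          else
            logHR = std::log((double)r) - std::log((double)cur.K);
          have = true;
        }
        break;
      }
      case 3: {  // add or remove a node (uniform label insertion)
        if (R::unif_rand() < 0.5) {  // add
          if (cur.n >= n_max) break;
          int p = unif_index(cur.n + 1);  // parent label 0..n
          std::vector<int> row;
          if (!draw_event_row(cur.K, lambda_s, lambda_c, max_abs_delta, row)) break;
          std::vector<std::vector<int> > ch = children_of(cur);
          std::vector<int> adopt;
          int cp = (int)ch[p].size();
          for (int j = 0; j < cp; ++j)
            if (R::unif_rand() < 0.5) adopt.push_back(ch[p][j]);
          int L = 1 + unif_index(cur.n + 1);
          cand = insert_node(cur, L, p, row, adopt);
          logHR = std::log(cur.n + 1.0) - event_draw_logq(row, lambda_s, lambda_c, cur.K)
                  + cp * std::log(2.0);
          have = true;
        } else {  // remove
          if (cur.n <= n_min || cur.n < 1) break;
          int i = 1 + unif_index(cur.n);
          std::vector<std::vector<int> > ch = children_of(cur);
          int ctot = (int)ch[i].size() + (int)ch[cur.parent[i - 1]].size() - 1;
          double lq = event_draw_logq(cur.ev[i - 1], lambda_s, lambda_c, cur.K);
          cand = delete_node(cur, i);
          logHR = lq - ctot * std::log(2.0) - std::log((double)cur.n);
          have = true;
        }
        break;
      }
      case 4: {  // condense an edge or split a node
        if (R::unif_rand() < 0.5) {  // condense child into parent
          if (cur.n <= n_min || cur.n < 2) break;
          std::vector<int> edges;  // child labels whose parent is non-root
          for (int i = 1; i <= cur.n; ++i)
            if (cur.parent[i - 1] != 0) edges.push_back(i);
          int E = (int)edges.size();
          if (E == 0) break;
          int c = edges[unif_index(E)];
          int up = cur.parent[c - 1];
          bool overlap = false;
          int rmerged = 0;
          for (int k = 0; k < cur.K; ++k) {
            if (cur.ev[c - 1][k] != 0 && cur.ev[up - 1][k] != 0) { overlap = true; break; }
            if (cur.ev[c - 1][k] != 0 || cur.ev[up - 1][k] != 0) ++rmerged;
          }
          if (overlap) break;  // merged deltas could not be re-partitioned
          TreeState merged = cur;
          for (int k = 0; k < cur.K; ++k) merged.ev[up - 1][k] += cur.ev[c - 1][k];
          cand = delete_node(merged, c);
          std::vector<std::vector<int> > ch = children_of(cur);
          int cu = (int)ch[up].size() - 1 + (int)ch[c].size();  // children of merged node
          // reverse: split the merged node into the exact ordered bipartition
          int Sy = 0;
          for (int i = 0; i < cand.n; ++i) {
            int rr = 0;
            for (int k = 0; k < cand.K; ++k)
              if (cand.ev[i][k] != 0) ++rr;
            if (rr >= 2) ++Sy;
          }
          if (rmerged > 30) break;  // overflow guard; never triggered at realistic sizes
          // reverse: split the merged node with the exact ordered bipartition,
          // the exact child subset, and the removed node's label slot
          double npart_r = (double)((1L << rmerged) - 2L);
          logHR = -std::log((double)Sy) - std::log(npart_r)
                  - cu * std::log(2.0) - std::log((double)cand.n + 1.0)
                  + std::log((double)E);
          have = true;
        } else {  // split a node with >= 2 entries
          if (cur.n >= n_max || cur.n < 1) break;
          std::vector<int> cands;
          for (int i = 1; i <= cur.n; ++i) {
            int rr = 0;
            for (int k = 0; k < cur.K; ++k)
              if (cur.ev[i - 1][k] != 0) ++rr;
            if (rr >= 2) cands.push_back(i);
          }
          int S = (int)cands.size();
          if (S == 0) break;
          int usel = cands[unif_index(S)];
          std::vector<int> nz;
          for (int k = 0; k < cur.K; ++k)
            if (cur.ev[usel - 1][k] != 0) nz.push_back(k);
          int r = (int)nz.size();
          if (r > 30) break;
          long npart_l = (1L << r) - 2L;
          double npart = (double)npart_l;
          long code = 1L + (long)(R::unif_rand() * npart);
          if (code > npart_l) code = npart_l;
          // bits of code: entries with a set bit go to the new child; codes
          // 1 .. 2^r-2 are exactly the proper nonempty bipartitions
          std::vector<int> keep(cur.K, 0), give(cur.K, 0);
          bool any_keep = false, any_give = false;
          for (int b = 0; b < r; ++b) {
            if ((code >> b) & 1L) { give[nz[b]] = cur.ev[usel - 1][nz[b]]; any_give = true; }
            else { keep[nz[b]] = cur.ev[usel - 1][nz[b]]; any_keep = true; }
          }
          if (!any_keep || !any_give) break;  // unreachable by construction; guard anyway
          TreeState half = cur;
          half.ev[usel - 1] = keep;
          std::vector<std::vector<int> > ch = children_of(cur);
          int cu = (int)ch[usel].size();
          std::vector<int> adopt;
          for (int j = 0; j < cu; ++j)
            if (R::unif_rand() < 0.5) adopt.push_back(ch[usel][j]);
          int L = 1 + unif_index(cur.n + 1);
          cand = insert_node(half, L, usel, give, adopt);
          // reverse: condense that edge in the candidate
          std::vector<int> redges;
          for (int i = 1; i <= cand.n; ++i)
            if (cand.parent[i - 1] != 0) redges.push_back(i);
          logHR = -std::log((double)redges.size())
                  + std::log((double)S) + std::log(npart) + cu * std::log(2.0)
                  + std::log(cur.n + 1.0);
          have = true;
        }
        break;
      }
      case 5: {  // genotype-preserving prune & reattach
        if (cur.n < 2) break;
        std::vector<std::vector<int> > gen = genotypes_of(cur);
        double base = event_prior_total(cur, lambda_s, lambda_c);
        std::vector<GpCand> nb;
        std::vector<double> lp;
        double logUx = gp_neighbourhood(cur, gen, lambda_s, lambda_c, base,
                                        max_abs_delta, &nb, &lp);
        if (nb.empty()) break;
        // sample proportionally to exp(event prior)
        double mx = lp[0];
        for (size_t j = 1; j < lp.size(); ++j) if (lp[j] > mx) mx = lp[j];
        double tot = 0.0;
        for (size_t j = 0; j < lp.size(); ++j) tot += std::exp(lp[j] - mx);
        double draw = R::unif_rand() * tot, acc2 = 0.0;
        size_t sel = lp.size() - 1;
        for (size_t j = 0; j < lp.size(); ++j) {
          acc2 += std::exp(lp[j] - mx);
          if (draw <= acc2) { sel = j; break; }
        }
        cand = cur;
        {
          int i = nb[sel].node, t = nb[sel].target;
          cand.parent[i - 1] = t;
          for (int k = 0; k < cand.K; ++k)
            cand.ev[i - 1][k] = gen[i][k] - gen[t][k];
        }
        double base_y = lp[sel];
        double logUy = gp_neighbourhood(cand, gen, lambda_s, lambda_c, base_y,
                                        max_abs_delta, NULL, NULL);
        // acceptance collapses to U(x)/U(y)
        double new_score = cur_score + (base_y - base);
        double log_acc = logUx - logUy;
        if (std::log(R::unif_rand()) < log_acc) {
          cur = cand;
          cur_score = new_score;
          ++n_acc[mv];
          accepted = true;
          if (cur_score > best_score) {
            best = cur; best_nu = nu; best_score = cur_score; best_iter = it;
            imp_iter.push_back(it); imp_score.push_back(best_score);
          }
        }
        have = false;  // handled here
        break;
      }
      case 6: {  // random walk on log(nu)
        if (nu_sd <= 0) { cand_nu = nu; }
        else cand_nu = std::exp(std::log(nu) + R::norm_rand() * nu_sd);
        if (cand_nu < nu_min || cand_nu > nu_max) break;
        cand = cur;
        nu_changed = true;
        have = true;
        break;
      }
    }

    if (have) {
      double cand_score;
      if (nu_changed) {
        std::vector<double> rv2 = root_loglik_vec(cur.rootp, D, sizes, Nj, cand_nu, eta, multinomial);
        cand_score = tree_score_ws(cand, ws, Dp, m, szp, wp, rv2, Nj, cand_nu, eta,
                                   multinomial, score_max, lambda_s, lambda_c, kappa, M);
        if (std::isfinite(cand_score) &&
            std::log(R::unif_rand()) < (cand_score - cur_score) + logHR) {
          nu = cand_nu;
          rootv = rv2;
          cur_score = cand_score;
          ++n_acc[mv];
          accepted = true;
        }
      } else {
        cand_score = tree_score_ws(cand, ws, Dp, m, szp, wp, rootv, Nj, nu, eta,
                                    multinomial, score_max, lambda_s, lambda_c, kappa, M);
        if (std::isfinite(cand_score) &&
            std::log(R::unif_rand()) < (cand_score - cur_score) + logHR) {
          cur = cand;
          cur_score = cand_score;
          ++n_acc[mv];
          accepted = true;
        }
      }
      if (accepted && cur_score > best_score) {
        best = cur; best_nu = nu; best_score = cur_score; best_iter = it;
        imp_iter.push_back(it); imp_score.push_back(best_score);
      }
    }

    if (track_states) visits[state_key(cur)] += 1.0;
  }

  List beststate = state_to_r(best);
  List out = List::create(
      _["best"] = beststate, _["best_nu"] = best_nu, _["best_score"] = best_score,
      _["best_iteration"] = best_iter,
      _["final"] = state_to_r(cur), _["final_nu"] = nu, _["final_score"] = cur_score,
      _["proposed"] = IntegerVector(n_prop.begin(), n_prop.end()),
      _["accepted"] = IntegerVector(n_acc.begin(), n_acc.end()),
      _["improvement_iter"] = NumericVector(imp_iter.begin(), imp_iter.end()),
      _["improvement_score"] = NumericVector(imp_score.begin(), imp_score.end()));
  if (track_states) {
    NumericVector v((int)visits.size());
    CharacterVector nm((int)visits.size());
    int j = 0;
    for (std::map<std::string, double>::iterator it2 = visits.begin(); it2 != visits.end(); ++it2) {
      nm[j] = it2->first;
      v[j] = it2->second;
      ++j;
    }
    v.attr("names") = nm;
    out["visits"] = v;
  }
  return out;
}
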