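// IIT 3.0 core: repertoires, earth mover's distance, mechanism-level phi,
// concepts, cause-effect structures and system-level big Phi with
// unidirectional-cut MIP search.
//
// Conventions (fixed throughout the package):
//  * states are bit masks, little-endian: node 1 <-> least significant bit;
//  * the TPM is state-by-node: 2^n rows (past collective state) x n columns
//    (probability that the node is ON at the next step), nodes conditionally
//    independent given the past state;
//  * ground metric for repertoire EMD is the Hamming distance between
//    purview states; effect repertoires factorise over nodes, so their EMD
//    reduces to the sum of per-node marginal differences.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline int pc(unsigned x) { return __builtin_popcount(x); }

static const double EPS = 1e-12;
static const double PHI_EPS = 1e-10;

// ---------------------------------------------------------------------------
// Exact transportation problem (min-cost flow, successive shortest paths).
// Sizes here are tiny (<= ~33 points a side), SPFA is plenty.
// ---------------------------------------------------------------------------

namespace mcmf {

struct Edge { int to; double cap; double cost; int rev; };

static std::vector<std::vector<Edge> > G;

static void add_edge(int u, int v, double cap, double cost) {
  G[u].push_back(Edge{v, cap, cost, (int)G[v].size()});
  G[v].push_back(Edge{u, 0.0, -cost, (int)G[u].size() - 1});
}

// a: supplies, b: demands, cost row-major (a.size() x b.size()).
// Returns the minimum total transport cost; ships min(sum a, sum b).
// Successive shortest paths with Dijkstra on reduced costs (Johnson
// potentials); all original costs are non-negative, so zero initial
// potentials are valid.
static double solve(const std::vector<double>& a, const std::vector<double>& b,
                    const std::vector<double>& cost) {
  const int na = (int)a.size(), nb = (int)b.size();
  const int N = na + nb + 2, S = na + nb, T = na + nb + 1;
  G.assign(N, std::vector<Edge>());
  for (int i = 0; i < na; ++i) add_edge(S, i, a[i], 0.0);
  for (int j = 0; j < nb; ++j) add_edge(na + j, T, b[j], 0.0);
  const double INF = std::numeric_limits<double>::infinity();
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j)
      add_edge(i, na + j, INF, cost[i * nb + j]);

  double total = 0.0;
  std::vector<double> dist(N), pot(N, 0.0);
  std::vector<int> pv(N), pe(N);
  std::vector<char> done(N);
  for (;;) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), 0);
    dist[S] = 0.0;
    for (;;) {
      int u = -1;
      double du = INF;
      for (int v = 0; v < N; ++v)
        if (!done[v] && dist[v] < du) { du = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      if (u == T) continue;
      for (int k = 0; k < (int)G[u].size(); ++k) {
        const Edge& e = G[u][k];
        if (e.cap <= EPS || done[e.to]) continue;
        double rc = e.cost + pot[u] - pot[e.to];
        if (rc < 0) rc = 0;  // guard against floating noise
        if (dist[u] + rc < dist[e.to] - 1e-15) {
          dist[e.to] = dist[u] + rc;
          pv[e.to] = u; pe[e.to] = k;
        }
      }
    }
    if (!std::isfinite(dist[T])) break;
    for (int v = 0; v < N; ++v)
      if (std::isfinite(dist[v])) pot[v] += dist[v];
    double f = INF;
    for (int v = T; v != S; v = pv[v]) f = std::min(f, G[pv[v]][pe[v]].cap);
    if (!(f > EPS)) break;
    double pathcost = 0.0;
    for (int v = T; v != S; v = pv[v]) {
      Edge& e = G[pv[v]][pe[v]];
      pathcost += e.cost;
      e.cap -= f;
      G[v][e.rev].cap += f;
    }
    total += f * pathcost;
  }
  return total;
}

} // namespace mcmf

// EMD between two distributions over the states of `nbits` binary nodes,
// Hamming ground metric. Mass shared between identical states stays put
// (valid because Hamming is a metric), which keeps the flow problem small.
static double emd_hamming_core(const double* p, const double* q, int m) {
  std::vector<double> a, b;
  std::vector<int> ai, bi;
  for (int s = 0; s < m; ++s) {
    double d = p[s] - q[s];
    if (d > EPS) { a.push_back(d); ai.push_back(s); }
    else if (d < -EPS) { b.push_back(-d); bi.push_back(s); }
  }
  if (a.empty() || b.empty()) return 0.0;
  std::vector<double> cost(a.size() * b.size());
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j)
      cost[i * b.size() + j] = (double)pc((unsigned)(ai[i] ^ bi[j]));
  return mcmf::solve(a, b, cost);
}

// ---------------------------------------------------------------------------
// System precomputations
// ---------------------------------------------------------------------------

struct Mice {
  double phi;
  int purview;                  // bit mask
  std::vector<double> rep;      // cause: distribution over compact purview
                                // states; effect: per-node ON marginals
  bool undef;
};

struct Concept {
  int mech;
  double phi;
  Mice cause, effect;
  // expanded over the full node set (filled when a CES is assembled):
  std::vector<double> exCause;  // 2^n distribution
  std::vector<double> exEff;    // n ON-marginals
};

struct IITSystem {
  int n, ns, state;
  std::vector<double> tpm;                       // ns x n row-major
  std::vector<double> Emarg;                     // ns x n: [M*n + j]
  std::vector<std::vector<int> > expand;         // [Z][zc] -> state mask
  std::vector<std::vector<std::vector<double> > > causeL; // [i][Z][zc]
  std::vector<std::vector<double> > crCache;     // [M*ns + Z]
  std::vector<char> crHave, crUndef;

  void init(const std::vector<double>& tpm_, int n_, int state_) {
    n = n_; ns = 1 << n; state = state_; tpm = tpm_;
    expand.assign(ns, std::vector<int>());
    for (int Z = 0; Z < ns; ++Z) {
      int k = pc(Z);
      expand[Z].resize(1 << k);
      for (int zc = 0; zc < (1 << k); ++zc) {
        int mask = 0, bit = 0;
        for (int i = 0; i < n; ++i)
          if (Z >> i & 1) { if (zc >> bit & 1) mask |= 1 << i; ++bit; }
        expand[Z][zc] = mask;
      }
    }
    // Emarg[M][j]: P(x_j ON | nodes in M clamped to `state`, rest uniform)
    Emarg.assign((size_t)ns * n, 0.0);
    for (int M = 0; M < ns; ++M) {
      int fixed = M & state, free_ = (~M) & (ns - 1);
      const std::vector<int>& ws = expand[free_];
      double inv = 1.0 / ws.size();
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (size_t w = 0; w < ws.size(); ++w) s += tpm[(size_t)(fixed | ws[w]) * n + j];
        Emarg[(size_t)M * n + j] = s * inv;
      }
    }
    // causeL[i][Z][zc]: mean over non-purview past states of the likelihood
    // that node i is in its current state given past (z, w)
    causeL.assign(n, std::vector<std::vector<double> >(ns));
    for (int i = 0; i < n; ++i) {
      bool on = (state >> i) & 1;
      for (int Z = 0; Z < ns; ++Z) {
        int free_ = (~Z) & (ns - 1);
        const std::vector<int>& zs = expand[Z];
        const std::vector<int>& ws = expand[free_];
        double inv = 1.0 / ws.size();
        std::vector<double>& v = causeL[i][Z];
        v.resize(zs.size());
        for (size_t zi = 0; zi < zs.size(); ++zi) {
          double s = 0.0;
          for (size_t w = 0; w < ws.size(); ++w) {
            double pr = tpm[(size_t)(zs[zi] | ws[w]) * n + i];
            s += on ? pr : (1.0 - pr);
          }
          v[zi] = s * inv;
        }
      }
    }
    crCache.assign((size_t)ns * ns, std::vector<double>());
    crHave.assign((size_t)ns * ns, 0);
    crUndef.assign((size_t)ns * ns, 0);
  }

  inline int compress(int mask, int Z) const {
    int idx = 0, bit = 0;
    for (int i = 0; i < n; ++i)
      if (Z >> i & 1) { if (mask >> i & 1) idx |= 1 << bit; ++bit; }
    return idx;
  }

  // Cause repertoire of mechanism M (in its current state) over purview Z,
  // mechanism nodes as independent virtual elements, normalised.
  // Undefined (all-zero likelihood) repertoires fall back to uniform with a
  // flag; callers treat them as phi = 0.
  const std::vector<double>& causeRep(int M, int Z, bool& undef) {
    size_t key = (size_t)M * ns + Z;
    if (!crHave[key]) {
      int m = 1 << pc(Z);
      std::vector<double> v((size_t)m, 1.0);
      for (int i = 0; i < n; ++i)
        if (M >> i & 1) {
          const std::vector<double>& L = causeL[i][Z];
          for (int zc = 0; zc < m; ++zc) v[zc] *= L[zc];
        }
      double s = 0.0;
      for (int zc = 0; zc < m; ++zc) s += v[zc];
      if (s <= 0.0) {
        for (int zc = 0; zc < m; ++zc) v[zc] = 1.0 / m;
        crUndef[key] = 1;
      } else {
        for (int zc = 0; zc < m; ++zc) v[zc] /= s;
      }
      crCache[key] = v;
      crHave[key] = 1;
    }
    undef = crUndef[key] != 0;
    return crCache[key];
  }

  bool reachable(int s) const {
    for (int r = 0; r < ns; ++r) {
      bool ok = true;
      for (int i = 0; i < n && ok; ++i) {
        double pr = tpm[(size_t)r * n + i];
        double lik = (s >> i & 1) ? pr : 1.0 - pr;
        if (!(lik > 0.0)) ok = false;
      }
      if (ok) return true;
    }
    return false;
  }

  // ----- mechanism-level phi ------------------------------------------------

  // Effect side: repertoires are products, EMD = sum of marginal differences.
  Mice miceEffect(int M) {
    Mice best; best.phi = -1.0; best.purview = 0; best.undef = false;
    int low = M & (-M), Mrest = M ^ low;
    std::vector<double> pm(n), qm(n);
    for (int Z = 1; Z < ns; ++Z) {
      for (int j = 0; j < n; ++j)
        if (Z >> j & 1) pm[j] = Emarg[(size_t)M * n + j];
      double phiZ = std::numeric_limits<double>::infinity();
      for (int M1 = Mrest;; M1 = (M1 - 1) & Mrest) { // submasks of Mrest
        int M2 = M ^ M1;
        for (int Z1 = Z;; Z1 = (Z1 - 1) & Z) {       // submasks of Z
          int Z2 = Z ^ Z1;
          if (!(M1 == 0 && Z1 == 0)) {
            double d = 0.0;
            for (int j = 0; j < n; ++j)
              if (Z >> j & 1) {
                int Mk = (Z1 >> j & 1) ? M1 : M2;
                d += std::fabs(pm[j] - Emarg[(size_t)Mk * n + j]);
              }
            if (d < phiZ) phiZ = d;
          }
          if (Z1 == 0) break;
        }
        if (M1 == 0) break;
      }
      if (phiZ > best.phi + PHI_EPS ||
          (std::fabs(phiZ - best.phi) <= PHI_EPS && pc(Z) > pc(best.purview))) {
        best.phi = phiZ; best.purview = Z;
      }
    }
    best.rep.clear();
    for (int j = 0; j < n; ++j)
      if (best.purview >> j & 1) best.rep.push_back(Emarg[(size_t)M * n + j]);
    if (best.phi < 0) best.phi = 0;
    return best;
  }

  Mice miceCause(int M) {
    Mice best; best.phi = -1.0; best.purview = 0; best.undef = false;
    int low = M & (-M), Mrest = M ^ low;
    for (int Z = 1; Z < ns; ++Z) {
      int m = 1 << pc(Z);
      bool undef;
      const std::vector<double> p = causeRep(M, Z, undef); // copy: cache may grow
      double phiZ;
      bool zundef = undef;
      if (undef) {
        phiZ = 0.0;
      } else {
        phiZ = std::numeric_limits<double>::infinity();
        std::vector<double> q((size_t)m);
        for (int M1 = Mrest;; M1 = (M1 - 1) & Mrest) {
          int M2 = M ^ M1;
          for (int Z1 = Z;; Z1 = (Z1 - 1) & Z) {
            int Z2 = Z ^ Z1;
            if (!(M1 == 0 && Z1 == 0)) {
              bool u1 = false, u2 = false;
              const std::vector<double>* f1 = Z1 ? &causeRep(M1, Z1, u1) : 0;
              const std::vector<double>* f2 = Z2 ? &causeRep(M2, Z2, u2) : 0;
              double tv = 0.0;
              for (int zc = 0; zc < m; ++zc) {
                int zmask = expand[Z][zc];
                double qv = 1.0;
                if (f1) qv *= (*f1)[compress(zmask & Z1, Z1)];
                if (f2) qv *= (*f2)[compress(zmask & Z2, Z2)];
                q[zc] = qv;
                tv += std::fabs(p[zc] - qv);
              }
              tv *= 0.5; // total variation: a lower bound on the Hamming EMD
              if (tv < phiZ) {
                double d = tv > EPS ? emd_hamming_core(p.data(), q.data(), m) : 0.0;
                if (d < phiZ) phiZ = d;
              }
            }
            if (Z1 == 0) break;
          }
          if (M1 == 0) break;
        }
      }
      if (phiZ > best.phi + PHI_EPS ||
          (std::fabs(phiZ - best.phi) <= PHI_EPS && pc(Z) > pc(best.purview))) {
        best.phi = phiZ; best.purview = Z; best.undef = zundef;
      }
    }
    bool u;
    best.rep = causeRep(M, best.purview, u);
    if (best.phi < 0) best.phi = 0;
    return best;
  }

  bool concept_(int M, Concept& out) {
    Mice c = miceCause(M);
    if (c.phi <= PHI_EPS) return false;
    Mice e = miceEffect(M);
    if (e.phi <= PHI_EPS) return false;
    out.mech = M;
    out.phi = std::min(c.phi, e.phi);
    out.cause = c;
    out.effect = e;
    return true;
  }

  // Expand a concept's repertoires over the full node set of this system.
  void expandConcept(Concept& c) {
    int Zc = c.cause.purview;
    double unif = 1.0 / (1 << (n - pc(Zc)));
    c.exCause.assign((size_t)ns, 0.0);
    for (int s = 0; s < ns; ++s)
      c.exCause[s] = c.cause.rep[compress(s & Zc, Zc)] * unif;
    c.exEff.assign((size_t)n, 0.0);
    int bit = 0;
    for (int j = 0; j < n; ++j) {
      if (c.effect.purview >> j & 1) c.exEff[j] = c.effect.rep[bit++];
      else c.exEff[j] = Emarg[j]; // M = 0: unconstrained effect marginal
    }
  }

  std::vector<Concept> ces() {
    std::vector<Concept> out;
    for (int M = 1; M < ns; ++M) {
      Concept c;
      if (concept_(M, c)) { expandConcept(c); out.push_back(c); }
    }
    return out;
  }

  Concept nullConcept() {
    Concept c;
    c.mech = 0; c.phi = 0.0;
    c.exCause.assign((size_t)ns, 1.0 / ns);
    c.exEff.assign((size_t)n, 0.0);
    for (int j = 0; j < n; ++j) c.exEff[j] = Emarg[j];
    c.cause.purview = ns - 1; c.effect.purview = ns - 1;
    return c;
  }
};

// Ground distance between two (expanded) concepts: cause-side Hamming EMD
// plus effect-side sum of marginal differences.
static double concept_distance(const Concept& a, const Concept& b, int n) {
  double d = emd_hamming_core(a.exCause.data(), b.exCause.data(), 1 << n);
  for (int j = 0; j < n; ++j) d += std::fabs(a.exEff[j] - b.exEff[j]);
  return d;
}

// Extended EMD between two cause-effect structures. phi mass may move
// between concepts or be created/destroyed at the null concept of the
// intact system.
static double ces_distance_core(const std::vector<Concept>& A,
                                const std::vector<Concept>& B,
                                const Concept& null_, int n) {
  double totA = 0.0, totB = 0.0;
  for (size_t i = 0; i < A.size(); ++i) totA += A[i].phi;
  for (size_t j = 0; j < B.size(); ++j) totB += B[j].phi;
  if (totA <= EPS && totB <= EPS) return 0.0;
  size_t na = A.size() + 1, nb = B.size() + 1;
  std::vector<double> a(na), b(nb), cost(na * nb);
  for (size_t i = 0; i < A.size(); ++i) a[i] = A[i].phi;
  a[na - 1] = totB;
  for (size_t j = 0; j < B.size(); ++j) b[j] = B[j].phi;
  b[nb - 1] = totA;
  for (size_t i = 0; i < A.size(); ++i)
    for (size_t j = 0; j < B.size(); ++j)
      cost[i * nb + j] = concept_distance(A[i], B[j], n);
  for (size_t i = 0; i < A.size(); ++i)
    cost[i * nb + (nb - 1)] = concept_distance(A[i], null_, n);
  for (size_t j = 0; j < B.size(); ++j)
    cost[(na - 1) * nb + j] = concept_distance(null_, B[j], n);
  cost[(na - 1) * nb + (nb - 1)] = 0.0;
  return mcmf::solve(a, b, cost);
}

// Sever edges from nodes in `from` into nodes in `to`: each target node's
// conditional is averaged uniformly over the severed inputs.
static std::vector<double> apply_cut_core(const std::vector<double>& tpm,
                                          int n, int from, int to) {
  int ns = 1 << n;
  std::vector<double> out = tpm;
  // enumerate submasks of `from`
  std::vector<int> ws;
  for (int w = from;; w = (w - 1) & from) { ws.push_back(w); if (w == 0) break; }
  double inv = 1.0 / ws.size();
  for (int j = 0; j < n; ++j) {
    if (!(to >> j & 1)) continue;
    for (int s = 0; s < ns; ++s) {
      int base = s & ~from;
      double acc = 0.0;
      for (size_t k = 0; k < ws.size(); ++k) acc += tpm[(size_t)(base | ws[k]) * n + j];
      out[(size_t)s * n + j] = acc * inv;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cut enumeration (canonical order: from-part size, then mask)
// ---------------------------------------------------------------------------

static std::vector<std::pair<int, int> > make_cuts(int n, const std::string& strategy) {
  int ns = 1 << n;
  std::vector<std::pair<int, int> > cuts;
  if (strategy == "one") {
    for (int i = 0; i < n; ++i) cuts.push_back(std::make_pair(1 << i, (ns - 1) ^ (1 << i)));
    for (int i = 0; i < n; ++i) cuts.push_back(std::make_pair((ns - 1) ^ (1 << i), 1 << i));
  } else { // exhaustive: all ordered non-trivial bipartitions
    std::vector<std::pair<int, int> > raw;
    for (int A = 1; A < ns - 1; ++A) raw.push_back(std::make_pair(A, (ns - 1) ^ A));
    std::stable_sort(raw.begin(), raw.end(),
                     [](const std::pair<int, int>& x, const std::pair<int, int>& y) {
                       int px = pc(x.first), py = pc(y.first);
                       return px != py ? px < py : x.first < y.first;
                     });
    cuts = raw;
  }
  return cuts;
}

// ---------------------------------------------------------------------------
// Helpers for the R interface
// ---------------------------------------------------------------------------

static std::vector<double> tpm_to_vec(const NumericMatrix& tpm, int& n) {
  n = tpm.ncol();
  int ns = 1 << n;
  if (tpm.nrow() != ns) stop("TPM must have 2^n rows for n columns");
  std::vector<double> v((size_t)ns * n);
  for (int s = 0; s < ns; ++s)
    for (int j = 0; j < n; ++j) {
      double p = tpm(s, j);
      if (!R_finite(p) || p < 0.0 || p > 1.0) stop("TPM entries must lie in [0, 1]");
      v[(size_t)s * n + j] = p;
    }
  return v;
}

static int state_to_mask(const IntegerVector& state, int n) {
  if (state.size() != n) stop("state must have one bit per node");
  int mask = 0;
  for (int i = 0; i < n; ++i) {
    if (state[i] != 0 && state[i] != 1) stop("state must be binary");
    if (state[i]) mask |= 1 << i;
  }
  return mask;
}

static int nodes_to_mask(const IntegerVector& nodes, int n) {
  int mask = 0;
  for (int k = 0; k < nodes.size(); ++k) {
    int i = nodes[k];
    if (i < 1 || i > n) stop("node index out of range");
    mask |= 1 << (i - 1);
  }
  return mask;
}

static IntegerVector mask_to_nodes(int mask, int n) {
  std::vector<int> v;
  for (int i = 0; i < n; ++i) if (mask >> i & 1) v.push_back(i + 1);
  return wrap(v);
}

// ---------------------------------------------------------------------------
// Exported functions
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_emd_hamming(NumericVector p, NumericVector q) {
  int m = p.size();
  if (q.size() != m) stop("distributions must have equal length");
  int bits = 0;
  while ((1 << bits) < m) ++bits;
  if ((1 << bits) != m) stop("length must be a power of 2");
  std::vector<double> pv(p.begin(), p.end()), qv(q.begin(), q.end());
  return emd_hamming_core(pv.data(), qv.data(), m);
}

// [[Rcpp::export]]
double cpp_transport(NumericVector a, NumericVector b, NumericMatrix cost) {
  std::vector<double> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<double> cv((size_t)a.size() * b.size());
  for (int i = 0; i < a.size(); ++i)
    for (int j = 0; j < b.size(); ++j)
      cv[(size_t)i * b.size() + j] = cost(i, j);
  return mcmf::solve(av, bv, cv);
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_cut(NumericMatrix tpm, IntegerVector from, IntegerVector to) {
  int n;
  std::vector<double> v = tpm_to_vec(tpm, n);
  std::vector<double> out = apply_cut_core(v, n, nodes_to_mask(from, n), nodes_to_mask(to, n));
  NumericMatrix res(tpm.nrow(), n);
  for (int s = 0; s < tpm.nrow(); ++s)
    for (int j = 0; j < n; ++j) res(s, j) = out[(size_t)s * n + j];
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_effect_repertoire(NumericMatrix tpm, IntegerVector state,
                                    IntegerVector mechanism, IntegerVector purview) {
  int n;
  std::vector<double> v = tpm_to_vec(tpm, n);
  IITSystem sys; sys.init(v, n, state_to_mask(state, n));
  int M = nodes_to_mask(mechanism, n), Z = nodes_to_mask(purview, n);
  int m = 1 << pc(Z);
  NumericVector out(m);
  for (int zc = 0; zc < m; ++zc) {
    int zmask = sys.expand[Z][zc];
    double pr = 1.0;
    for (int j = 0; j < n; ++j)
      if (Z >> j & 1) {
        double pj = sys.Emarg[(size_t)M * n + j];
        pr *= (zmask >> j & 1) ? pj : 1.0 - pj;
      }
    out[zc] = pr;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cause_repertoire(NumericMatrix tpm, IntegerVector state,
                          IntegerVector mechanism, IntegerVector purview) {
  int n;
  std::vector<double> v = tpm_to_vec(tpm, n);
  IITSystem sys; sys.init(v, n, state_to_mask(state, n));
  int M = nodes_to_mask(mechanism, n), Z = nodes_to_mask(purview, n);
  bool undef = false;
  std::vector<double> rep = sys.causeRep(M, Z, undef);
  return List::create(_["distribution"] = wrap(rep), _["undefined"] = undef);
}

static List mice_to_list(const Mice& x, int n) {
  return List::create(_["phi"] = x.phi,
                      _["purview"] = mask_to_nodes(x.purview, n),
                      _["repertoire"] = wrap(x.rep),
                      _["undefined"] = x.undef);
}

// [[Rcpp::export]]
List cpp_concept(NumericMatrix tpm, IntegerVector state, IntegerVector mechanism) {
  int n;
  std::vector<double> v = tpm_to_vec(tpm, n);
  IITSystem sys; sys.init(v, n, state_to_mask(state, n));
  int M = nodes_to_mask(mechanism, n);
  if (M == 0) stop("mechanism must be non-empty");
  Mice c = sys.miceCause(M), e = sys.miceEffect(M);
  double phi = std::min(c.phi, e.phi);
  return List::create(_["mechanism"] = mask_to_nodes(M, n),
                      _["phi"] = phi > PHI_EPS ? phi : 0.0,
                      _["cause"] = mice_to_list(c, n),
                      _["effect"] = mice_to_list(e, n));
}

static List ces_to_list(const std::vector<Concept>& C, int n) {
  List out(C.size());
  for (size_t k = 0; k < C.size(); ++k) {
    const Concept& c = C[k];
    out[k] = List::create(_["mechanism"] = mask_to_nodes(c.mech, n),
                          _["phi"] = c.phi,
                          _["cause_purview"] = mask_to_nodes(c.cause.purview, n),
                          _["cause_phi"] = c.cause.phi,
                          _["cause_repertoire"] = wrap(c.cause.rep),
                          _["effect_purview"] = mask_to_nodes(c.effect.purview, n),
                          _["effect_phi"] = c.effect.phi,
                          _["effect_marginals"] = wrap(c.effect.rep));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_ces(NumericMatrix tpm, IntegerVector state) {
  int n;
  std::vector<double> v = tpm_to_vec(tpm, n);
  IITSystem sys; sys.init(v, n, state_to_mask(state, n));
  std::vector<Concept> C = sys.ces();
  return ces_to_list(C, n);
}

// [[Rcpp::export]]
double cpp_ces_distance(NumericMatrix tpm_a, NumericMatrix tpm_b, IntegerVector state) {
  int n;
  std::vector<double> va = tpm_to_vec(tpm_a, n);
  int n2;
  std::vector<double> vb = tpm_to_vec(tpm_b, n2);
  if (n2 != n) stop("TPMs must have the same number of nodes");
  int s = state_to_mask(state, n);
  IITSystem A; A.init(va, n, s);
  IITSystem B; B.init(vb, n, s);
  std::vector<Concept> CA = A.ces(), CB = B.ces();
  return ces_distance_core(CA, CB, A.nullConcept(), n);
}

static List big_phi_impl(const std::vector<double>& v, int n, int smask,
                         const std::string& strategy, bool want_ces) {
  IITSystem sys; sys.init(v, n, smask);
  List out;
  if (!sys.reachable(smask)) {
    out = List::create(_["phi"] = 0.0, _["mip_from"] = IntegerVector(0),
                       _["mip_to"] = IntegerVector(0), _["n_concepts"] = 0,
                       _["sum_small_phi"] = 0.0, _["unreachable"] = true,
                       _["cut_distances"] = NumericVector(0));
    if (want_ces) out["ces"] = List(0);
    return out;
  }
  std::vector<Concept> C = sys.ces();
  double sumphi = 0.0;
  for (size_t k = 0; k < C.size(); ++k) sumphi += C[k].phi;
  std::vector<std::pair<int, int> > cuts = make_cuts(n, strategy);
  NumericVector cutd(cuts.size(), NA_REAL);
  double best = std::numeric_limits<double>::infinity();
  int bestk = 0;
  if (C.empty()) {
    best = 0.0;
  } else {
    Concept null_ = sys.nullConcept();
    for (size_t k = 0; k < cuts.size(); ++k) {
      std::vector<double> tcut = apply_cut_core(sys.tpm, n, cuts[k].first, cuts[k].second);
      IITSystem sc; sc.init(tcut, n, smask);
      std::vector<Concept> Ck = sc.ces();
      double d = ces_distance_core(C, Ck, null_, n);
      cutd[k] = d;
      if (d < best - EPS) { best = d; bestk = (int)k; }
      if (best <= EPS) break;
    }
  }
  if (!(best >= 0)) best = 0.0;
  out = List::create(_["phi"] = std::max(best, 0.0),
                     _["mip_from"] = mask_to_nodes(cuts[bestk].first, n),
                     _["mip_to"] = mask_to_nodes(cuts[bestk].second, n),
                     _["n_concepts"] = (int)C.size(),
                     _["sum_small_phi"] = sumphi,
                     _["unreachable"] = false,
                     _["cut_distances"] = cutd);
  if (want_ces) out["ces"] = ces_to_list(C, n);
  return out;
}

// [[Rcpp::export]]
List cpp_big_phi(NumericMatrix tpm, IntegerVector state, std::string strategy,
                 bool want_ces = false) {
  int n;
  std::vector<double> v = tpm_to_vec(tpm, n);
  if (n < 2) stop("big phi requires at least 2 nodes");
  return big_phi_impl(v, n, state_to_mask(state, n), strategy, want_ces);
}

// [[Rcpp::export]]
NumericVector cpp_phi_all_states(NumericMatrix tpm, std::string strategy) {
  int n;
  std::vector<double> v = tpm_to_vec(tpm, n);
  if (n < 2) stop("big phi requires at least 2 nodes");
  int ns = 1 << n;
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    List r = big_phi_impl(v, n, s, strategy, false);
    out[s] = as<double>(r["phi"]);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
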