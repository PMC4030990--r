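// Core geometry, pull-move and search machinery.
//
// Conformations are n x 3 integer coordinate matrices. The cubic lattice is
// Z^3 with unit-step adjacency; the FCC lattice is the even sublattice of
// Z^3 (x+y+z even) with the 12 offsets that are permutations of (+-1,+-1,0).
// All hot loops live here; R wrappers validate inputs and own the API.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <unordered_set>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

typedef std::array<int, 3> Pt;
typedef std::vector<Pt> Chain;

static const int CUB[6][3] = {
  {1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
static const int FCCO[12][3] = {
  {1, 1, 0},  {1, -1, 0}, {-1, 1, 0}, {-1, -1, 0},
  {1, 0, 1},  {1, 0, -1}, {-1, 0, 1}, {-1, 0, -1},
  {0, 1, 1},  {0, 1, -1}, {0, -1, 1}, {0, -1, -1}};

static inline int noff(bool fcc) { return fcc ? 12 : 6; }
static inline const int (*offs(bool fcc))[3] { return fcc ? FCCO : CUB; }

static inline bool adjp(const Pt &a, const Pt &b, bool fcc) {
  int dx = std::abs(a[0] - b[0]);
  int dy = std::abs(a[1] - b[1]);
  int dz = std::abs(a[2] - b[2]);
  if (fcc) return dx <= 1 && dy <= 1 && dz <= 1 && dx + dy + dz == 2;
  return dx + dy + dz == 1;
}

// coordinates are bounded by chain length (< 4096) so 13 bits per axis
static inline int64_t pk(const Pt &p) {
  return ((int64_t)(p[0] + 4096) << 26) |
         ((int64_t)(p[1] + 4096) << 13) |
         (int64_t)(p[2] + 4096);
}

static Chain asChain(const IntegerMatrix &m) {
  Chain P(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) P[i] = {m(i, 0), m(i, 1), m(i, 2)};
  return P;
}

static IntegerMatrix asMat(const Chain &P) {
  IntegerMatrix m(P.size(), 3);
  for (size_t i = 0; i < P.size(); ++i) {
    m(i, 0) = P[i][0]; m(i, 1) = P[i][1]; m(i, 2) = P[i][2];
  }
  return m;
}

// 0 ok; 1 duplicate site; 2 broken bond; 3 FCC parity violation.
static int validate_chain(const Chain &P, bool fcc, int &bad) {
  if (fcc) {
    for (size_t i = 0; i < P.size(); ++i)
      if (((P[i][0] + P[i][1] + P[i][2]) % 2 + 2) % 2 != 0) {
        bad = (int)i; return 3;
      }
  }
  std::unordered_set<int64_t> seen;
  for (size_t i = 0; i < P.size(); ++i)
    if (!seen.insert(pk(P[i])).second) { bad = (int)i; return 1; }
  for (size_t i = 0; i + 1 < P.size(); ++i)
    if (!adjp(P[i], P[i + 1], fcc)) { bad = (int)i; return 2; }
  bad = -1;
  return 0;
}

// [[Rcpp::export]]
IntegerVector cpp_validate(IntegerMatrix coords, bool fcc) {
  Chain P = asChain(coords);
  int bad = -1;
  int code = validate_chain(P, fcc, bad);
  return IntegerVector::create(code, bad + 1); // 1-based index for R
}

// [[Rcpp::export]]
IntegerMatrix cpp_contacts(IntegerMatrix coords, bool fcc) {
  Chain P = asChain(coords);
  int n = P.size();
  std::vector<std::pair<int, int> > v;
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j)
      if (adjp(P[i], P[j], fcc)) v.push_back(std::make_pair(i, j));
  IntegerMatrix out(v.size(), 2);
  for (size_t r = 0; r < v.size(); ++r) {
    out(r, 0) = v[r].first + 1; // 1-based for R
    out(r, 1) = v[r].second + 1;
  }
  return out;
}

static double chain_energy(const Chain &P, bool fcc,
                           const IntegerVector &types,
                           const NumericMatrix &emat) {
  int n = P.size();
  double e = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j)
      if (adjp(P[i], P[j], fcc)) e += emat(types[i], types[j]);
  return e;
}

// [[Rcpp::export]]
double cpp_contact_energy(IntegerMatrix coords, bool fcc,
                          IntegerVector types, NumericMatrix emat) {
  Chain P = asChain(coords);
  return chain_energy(P, fcc, types, emat);
}

// [[Rcpp::export]]
int cpp_hh_contacts(IntegerMatrix coords, bool fcc, LogicalVector ish) {
  Chain P = asChain(coords);
  int n = P.size(), c = 0;
  for (int i = 0; i < n; ++i) {
    if (!ish[i]) continue;
    for (int j = i + 2; j < n; ++j)
      if (ish[j] && adjp(P[i], P[j], fcc)) ++c;
  }
  return c;
}

// ---------------------------------------------------------------------------
// Pull moves
//
// Move record: anchor residue index, direction (0 = pull propagates toward
// the head / lower indices, 1 = toward the tail), target site L the anchor
// moves to, optional auxiliary site C occupied by the adjacent residue in
// the pull direction, and the inclusive index range [lo,hi] of residues
// whose coordinates change.
// ---------------------------------------------------------------------------

struct Mv {
  int anchor, dir;
  Pt L, C;
  bool hasC;
  int lo, hi; // inclusive affected range; encodes the propagation extent
};

// Apply by the recorded extent. Generated moves are valid by construction;
// the R-level apply revalidates against a fresh enumeration for stale
// safety.
static void apply_mv(const Chain &P, const Mv &m, bool fcc,
                     Chain &out, int &lo, int &hi) {
  (void)fcc;
  out = P;
  int i = m.anchor;
  out[i] = m.L;
  lo = m.lo; hi = m.hi;
  if (m.dir == 0) {
    if (m.hasC) {
      out[i - 1] = m.C;
      for (int j = i - 2; j >= m.lo; --j) out[j] = P[j + 2];
    }
  } else {
    if (m.hasC) {
      out[i + 1] = m.C;
      for (int j = i + 2; j <= m.hi; ++j) out[j] = P[j - 2];
    }
  }
}

static bool mv_less(const Mv &a, const Mv &b) {
  if (a.anchor != b.anchor) return a.anchor < b.anchor;
  if (a.dir != b.dir) return a.dir < b.dir;
  for (int t = 0; t < 3; ++t) if (a.L[t] != b.L[t]) return a.L[t] < b.L[t];
  if (a.hasC != b.hasC) return a.hasC < b.hasC;
  for (int t = 0; t < 3; ++t) if (a.C[t] != b.C[t]) return a.C[t] < b.C[t];
  if (a.lo != b.lo) return a.lo < b.lo;
  return a.hi < b.hi;
}

static void enum_mvs(const Chain &P, bool fcc, std::vector<Mv> &res) {
  res.clear();
  int n = P.size();
  if (n < 2) return;
  std::unordered_set<int64_t> occ;
  for (int i = 0; i < n; ++i) occ.insert(pk(P[i]));
  int K = noff(fcc);
  const int (*OF)[3] = offs(fcc);
  const Pt Z = {0, 0, 0};

  std::vector<Mv> cand;
  Chain scratch;
  // single-site move (no auxiliary, no propagation)
  #define EMIT1(ANCH, DIR, LL)                                       \
    do {                                                             \
      Mv m_; m_.anchor = (ANCH); m_.dir = (DIR); m_.L = (LL);        \
      m_.hasC = false; m_.C = Z;                                     \
      m_.lo = m_.hi = (ANCH);                                        \
      cand.push_back(m_);                                            \
    } while (0)

  // Standard pull with auxiliary site: the anchor moves to L, its
  // neighbour in the pull direction to C, and the remaining residues are
  // pulled along previously occupied sites. One move variant is emitted
  // for every valid propagation extent: the chain may reconnect at the
  // first opportunity or keep sliding further (up to a full-chain slide).
  // Recording the extent in the move is what makes the set reversible:
  // the exact reverse of any pull is itself an emitted variant.
  auto emit_pulls_head = [&](int i, const Pt &L, const Pt &C) {
    scratch = P;
    scratch[i] = L;
    scratch[i - 1] = C;
    int j = i - 2;
    for (;;) {
      if (j < 0) {
        Mv m_; m_.anchor = i; m_.dir = 0; m_.L = L; m_.hasC = true;
        m_.C = C; m_.lo = 0; m_.hi = i;
        cand.push_back(m_);
        break;
      }
      if (adjp(P[j], scratch[j + 1], fcc)) {
        Mv m_; m_.anchor = i; m_.dir = 0; m_.L = L; m_.hasC = true;
        m_.C = C; m_.lo = j + 1; m_.hi = i;
        cand.push_back(m_);
      }
      scratch[j] = P[j + 2];
      --j;
    }
  };
  auto emit_pulls_tail = [&](int i, const Pt &L, const Pt &C) {
    scratch = P;
    scratch[i] = L;
    scratch[i + 1] = C;
    int j = i + 2;
    for (;;) {
      if (j >= n) {
        Mv m_; m_.anchor = i; m_.dir = 1; m_.L = L; m_.hasC = true;
        m_.C = C; m_.lo = i; m_.hi = n - 1;
        cand.push_back(m_);
        break;
      }
      if (adjp(P[j], scratch[j - 1], fcc)) {
        Mv m_; m_.anchor = i; m_.dir = 1; m_.L = L; m_.hasC = true;
        m_.C = C; m_.lo = i; m_.hi = j - 1;
        cand.push_back(m_);
      }
      scratch[j] = P[j - 2];
      ++j;
    }
  };

  // direction 0 (pull toward head): anchors 1 .. n-1
  for (int i = 1; i < n; ++i) {
    if (i < n - 1) {
      for (int a = 0; a < K; ++a) {
        Pt L = {P[i + 1][0] + OF[a][0], P[i + 1][1] + OF[a][1],
                P[i + 1][2] + OF[a][2]};
        if (occ.count(pk(L))) continue;
        for (int b = 0; b < K; ++b) {
          Pt C = {L[0] + OF[b][0], L[1] + OF[b][1], L[2] + OF[b][2]};
          if (!adjp(C, P[i], fcc)) continue;
          if (C == P[i - 1]) {
            EMIT1(i, 0, L);                   // single-site pull
          } else if (!occ.count(pk(C))) {
            emit_pulls_head(i, L, C);         // standard pull variants
          }
        }
      }
    } else {
      // tail-end drag: end residue jumps to L via bridge C adjacent to its
      // old site; the rest of the chain is pulled after it
      for (int b = 0; b < K; ++b) {
        Pt C = {P[n - 1][0] + OF[b][0], P[n - 1][1] + OF[b][1],
                P[n - 1][2] + OF[b][2]};
        bool isPrev = (C == P[n - 2]);
        if (!isPrev && occ.count(pk(C))) continue;
        for (int a = 0; a < K; ++a) {
          Pt L = {C[0] + OF[a][0], C[1] + OF[a][1], C[2] + OF[a][2]};
          if (occ.count(pk(L))) continue;
          if (isPrev) EMIT1(n - 1, 0, L);          // simple end move
          else        emit_pulls_head(n - 1, L, C);
        }
      }
    }
  }
  // direction 1 (pull toward tail): anchors 0 .. n-2
  for (int i = 0; i < n - 1; ++i) {
    if (i > 0) {
      for (int a = 0; a < K; ++a) {
        Pt L = {P[i - 1][0] + OF[a][0], P[i - 1][1] + OF[a][1],
                P[i - 1][2] + OF[a][2]};
        if (occ.count(pk(L))) continue;
        for (int b = 0; b < K; ++b) {
          Pt C = {L[0] + OF[b][0], L[1] + OF[b][1], L[2] + OF[b][2]};
          if (!adjp(C, P[i], fcc)) continue;
          if (C == P[i + 1]) continue;        // single-site already emitted above
          if (!occ.count(pk(C))) emit_pulls_tail(i, L, C);
        }
      }
    } else {
      // head-end drag
      for (int b = 0; b < K; ++b) {
        Pt C = {P[0][0] + OF[b][0], P[0][1] + OF[b][1], P[0][2] + OF[b][2]};
        bool isNext = (C == P[1]);
        if (!isNext && occ.count(pk(C))) continue;
        for (int a = 0; a < K; ++a) {
          Pt L = {C[0] + OF[a][0], C[1] + OF[a][1], C[2] + OF[a][2]};
          if (occ.count(pk(L))) continue;
          if (isNext) EMIT1(0, 1, L);
          else        emit_pulls_tail(0, L, C);
        }
      }
    }
  }
  #undef EMIT1
  std::sort(cand.begin(), cand.end(), mv_less);
  res.swap(cand);
}

static IntegerMatrix mvs_to_mat(const std::vector<Mv> &mv) {
  IntegerMatrix out(mv.size(), 11);
  for (size_t r = 0; r < mv.size(); ++r) {
    const Mv &m = mv[r];
    out(r, 0) = m.anchor; out(r, 1) = m.dir;
    out(r, 2) = m.L[0]; out(r, 3) = m.L[1]; out(r, 4) = m.L[2];
    out(r, 5) = m.hasC ? 1 : 0;
    out(r, 6) = m.C[0]; out(r, 7) = m.C[1]; out(r, 8) = m.C[2];
    out(r, 9) = m.lo; out(r, 10) = m.hi;
  }
  return out;
}

// columns: anchor0, dir, Lx, Ly, Lz, hasC, Cx, Cy, Cz, lo0, hi0
// [[Rcpp::export]]
IntegerMatrix cpp_enum_moves(IntegerMatrix coords, bool fcc) {
  Chain P = asChain(coords);
  std::vector<Mv> mv;
  enum_mvs(P, fcc, mv);
  return mvs_to_mat(mv);
}

static Mv row_to_mv(const IntegerVector &r) {
  Mv m;
  m.anchor = r[0]; m.dir = r[1];
  m.L = {r[2], r[3], r[4]};
  m.hasC = r[5] != 0;
  m.C = {r[6], r[7], r[8]};
  m.lo = r[9]; m.hi = r[10];
  return m;
}

// Validates the move against a fresh enumeration (stale-move safety),
// then applies. Returns NULL if the move is not currently legal.
// [[Rcpp::export]]
SEXP cpp_apply_move(IntegerMatrix coords, bool fcc, IntegerVector move) {
  Chain P = asChain(coords);
  Mv m = row_to_mv(move);
  std::vector<Mv> mv;
  enum_mvs(P, fcc, mv);
  bool legal = false;
  for (size_t r = 0; r < mv.size(); ++r) {
    const Mv &q = mv[r];
    if (q.anchor == m.anchor && q.dir == m.dir && q.L == m.L &&
        q.hasC == m.hasC && (!q.hasC || q.C == m.C) &&
        q.lo == m.lo && q.hi == m.hi) { legal = true; break; }
  }
  if (!legal) return R_NilValue;
  Chain out; int lo, hi;
  apply_mv(P, m, fcc, out, lo, hi);
  return List::create(_["coords"] = asMat(out),
                      _["lo"] = lo + 1, _["hi"] = hi + 1);
}

// All conformations one pull move away (with multiplicity), for BFS tests.
// [[Rcpp::export]]
List cpp_move_results(IntegerMatrix coords, bool fcc) {
  Chain P = asChain(coords);
  std::vector<Mv> mv;
  enum_mvs(P, fcc, mv);
  List out(mv.size());
  Chain o; int lo, hi;
  for (size_t r = 0; r < mv.size(); ++r) {
    apply_mv(P, mv[r], fcc, o, lo, hi);
    out[r] = asMat(o);
  }
  return out;
}

// Constant-time legality test for a single move record, mirroring the
// emission conditions of enum_mvs exactly (cross-checked against the
// enumerator in the test suite).
static bool mv_legal(const Chain &Q, const Mv &m, bool fcc,
                     const std::unordered_set<int64_t> &occ) {
  int n = Q.size();
  if (n < 2) return false;
  int i = m.anchor;
  if (i < 0 || i >= n) return false;
  if (occ.count(pk(m.L))) return false;
  if (!m.hasC) {
    if (m.lo != i || m.hi != i) return false;
    if (m.dir == 0) {
      if (i == 0) return false;
      if (i < n - 1)
        return adjp(m.L, Q[i + 1], fcc) && adjp(m.L, Q[i - 1], fcc);
      return adjp(m.L, Q[n - 2], fcc);   // simple tail end move
    }
    if (i != 0) return false;            // head-single only emitted at i = 0
    return adjp(m.L, Q[1], fcc);
  }
  if (occ.count(pk(m.C))) return false;
  if (!adjp(m.C, m.L, fcc) || !adjp(m.C, Q[i], fcc)) return false;
  if (m.dir == 0) {
    if (i == 0 || m.hi != i || m.lo < 0 || m.lo > i - 1) return false;
    if (i < n - 1 && !adjp(m.L, Q[i + 1], fcc)) return false;
    if (m.lo == 0) return true;          // full slide is always a valid stop
    Pt np = (m.lo == i - 1) ? m.C : Q[m.lo + 2];
    return adjp(Q[m.lo - 1], np, fcc);
  }
  if (i == n - 1 || m.lo != i || m.hi > n - 1 || m.hi < i + 1) return false;
  if (i > 0 && !adjp(m.L, Q[i - 1], fcc)) return false;
  if (m.hi == n - 1) return true;
  Pt np = (m.hi == i + 1) ? m.C : Q[m.hi - 2];
  return adjp(Q[m.hi + 1], np, fcc);
}

// [[Rcpp::export]]
bool cpp_mv_legal(IntegerMatrix coords, bool fcc, IntegerVector move) {
  Chain Q = asChain(coords);
  std::unordered_set<int64_t> occ;
  for (size_t i = 0; i < Q.size(); ++i) occ.insert(pk(Q[i]));
  return mv_legal(Q, row_to_mv(move), fcc, occ);
}

// Expected reverse of a move applied to P: pulling back along the same
// affected range from the opposite side.
static Mv reverse_of(const Chain &P, const Mv &m) {
  Mv r;
  r.hasC = m.hasC;
  if (!m.hasC) {
    r.anchor = m.anchor; r.dir = m.dir;
    r.L = P[m.anchor]; r.C = {0, 0, 0};
    r.lo = r.hi = m.anchor;
  } else if (m.dir == 0) { // moved [lo, anchor]; reverse pulls toward tail
    r.anchor = m.lo; r.dir = 1;
    r.L = P[m.lo]; r.C = P[m.lo + 1];
    r.lo = m.lo; r.hi = m.anchor;
  } else {                 // moved [anchor, hi]; reverse pulls toward head
    r.anchor = m.hi; r.dir = 0;
    r.L = P[m.hi]; r.C = P[m.hi - 1];
    r.lo = m.anchor; r.hi = m.hi;
  }
  return r;
}

// For every enumerated move: the result is a valid conformation, residues
// outside [lo,hi] are untouched, the reverse move is itself legal on the
// result, and applying it restores the original. Returns the 1-based index
// of the first offending move, or 0.
// [[Rcpp::export]]
int cpp_check_moves(IntegerMatrix coords, bool fcc) {
  Chain P = asChain(coords);
  std::vector<Mv> mv;
  enum_mvs(P, fcc, mv);
  Chain o, back; int lo, hi, l2, h2, bad;
  for (size_t r = 0; r < mv.size(); ++r) {
    apply_mv(P, mv[r], fcc, o, lo, hi);
    if (validate_chain(o, fcc, bad) != 0) return (int)r + 1;
    for (int j = 0; j < (int)P.size(); ++j)
      if ((j < lo || j > hi) && !(o[j] == P[j])) return (int)r + 1;
    Mv rev = reverse_of(P, mv[r]);
    std::unordered_set<int64_t> occ2;
    for (size_t q = 0; q < o.size(); ++q) occ2.insert(pk(o[q]));
    if (!mv_legal(o, rev, fcc, occ2)) return (int)r + 1;
    apply_mv(o, rev, fcc, back, l2, h2);
    if (!(back == P)) return (int)r + 1;
  }
  return 0;
}

// ---------------------------------------------------------------------------
// Self-avoiding walks: random generation and exhaustive enumeration
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_random_saw(int n, bool fcc, int max_restarts) {
  int K = noff(fcc);
  const int (*OF)[3] = offs(fcc);
  for (int attempt = 0; attempt <= max_restarts; ++attempt) {
    Chain P;
    P.push_back({0, 0, 0});
    std::unordered_set<int64_t> occ;
    occ.insert(pk(P[0]));
    bool dead = false;
    while ((int)P.size() < n) {
      Pt cur = P.back();
      Pt cand[12];
      int nc = 0;
      for (int a = 0; a < K; ++a) {
        Pt q = {cur[0] + OF[a][0], cur[1] + OF[a][1], cur[2] + OF[a][2]};
        if (!occ.count(pk(q))) cand[nc++] = q;
      }
      if (nc == 0) { dead = true; break; }
      int pick = (int)(unif_rand() * nc);
      if (pick >= nc) pick = nc - 1;
      P.push_back(cand[pick]);
      occ.insert(pk(cand[pick]));
    }
    if (!dead) return asMat(P);
  }
  return R_NilValue;
}

static void walk_dfs(Chain &P, std::unordered_set<int64_t> &occ, int n,
                     bool fcc, bool canonical, std::vector<Chain> *acc,
                     double *count) {
  if ((int)P.size() == n) {
    if (acc) acc->push_back(P);
    if (count) *count += 1.0;
    return;
  }
  int K = noff(fcc);
  const int (*OF)[3] = offs(fcc);
  // fixed canonical first step quotients the trivial first-bond symmetry
  int amax = (canonical && P.size() == 1) ? 1 : K;
  Pt cur = P.back();
  for (int a = 0; a < amax; ++a) {
    Pt q = {cur[0] + OF[a][0], cur[1] + OF[a][1], cur[2] + OF[a][2]};
    int64_t key = pk(q);
    if (occ.count(key)) continue;
    P.push_back(q);
    occ.insert(key);
    walk_dfs(P, occ, n, fcc, canonical, acc, count);
    P.pop_back();
    occ.erase(key);
  }
}

// [[Rcpp::export]]
List cpp_enumerate_walks(int n, bool fcc, bool canonical) {
  std::vector<Chain> acc;
  Chain P;
  P.push_back({0, 0, 0});
  std::unordered_set<int64_t> occ;
  occ.insert(pk(P[0]));
  walk_dfs(P, occ, n, fcc, canonical, &acc, NULL);
  List out(acc.size());
  for (size_t i = 0; i < acc.size(); ++i) out[i] = asMat(acc[i]);
  return out;
}

// [[Rcpp::export]]
double cpp_count_walks(int n, bool fcc, bool canonical) {
  double cnt = 0.0;
  Chain P;
  P.push_back({0, 0, 0});
  std::unordered_set<int64_t> occ;
  occ.insert(pk(P[0]));
  walk_dfs(P, occ, n, fcc, canonical, NULL, &cnt);
  return cnt;
}

struct MinAcc {
  double best;
  Chain witness;
  const IntegerVector *types;
  const NumericMatrix *emat;
  bool fcc;
};

static void min_dfs(Chain &P, std::unordered_set<int64_t> &occ, int n,
                    MinAcc &st) {
  if ((int)P.size() == n) {
    double e = chain_energy(P, st.fcc, *st.types, *st.emat);
    if (e < st.best) { st.best = e; st.witness = P; }
    return;
  }
  int K = noff(st.fcc);
  const int (*OF)[3] = offs(st.fcc);
  int amax = (P.size() == 1) ? 1 : K; // canonical first step: energy is symmetry-invariant
  Pt cur = P.back();
  for (int a = 0; a < amax; ++a) {
    Pt q = {cur[0] + OF[a][0], cur[1] + OF[a][1], cur[2] + OF[a][2]};
    int64_t key = pk(q);
    if (occ.count(key)) continue;
    P.push_back(q);
    occ.insert(key);
    min_dfs(P, occ, n, st);
    P.pop_back();
    occ.erase(key);
  }
}

// [[Rcpp::export]]
List cpp_enum_min_energy(int n, bool fcc, IntegerVector types,
                         NumericMatrix emat) {
  MinAcc st;
  st.best = R_PosInf;
  st.types = &types;
  st.emat = &emat;
  st.fcc = fcc;
  Chain P;
  P.push_back({0, 0, 0});
  std::unordered_set<int64_t> occ;
  occ.insert(pk(P[0]));
  min_dfs(P, occ, n, st);
  return List::create(_["min_energy"] = st.best,
                      _["witness"] = asMat(st.witness));
}

// ---------------------------------------------------------------------------
// Greedy descent and the population search loop
// ---------------------------------------------------------------------------

// Greedy pull-move descent to a local minimum. Every energy evaluation is
// counted: one for the starting conformation, one per candidate per sweep.
// Among strictly improving moves one is chosen uniformly at random.
// [[Rcpp::export]]
List cpp_greedy_descent(IntegerMatrix coords, bool fcc, IntegerVector types,
                        NumericMatrix emat) {
  Chain P = asChain(coords);
  double E = chain_energy(P, fcc, types, emat);
  double evals = 1.0;
  std::vector<Mv> mv;
  Chain o; int lo, hi;
  for (;;) {
    enum_mvs(P, fcc, mv);
    if (mv.empty()) break;
    std::vector<Chain> imp;
    std::vector<double> impE;
    for (size_t r = 0; r < mv.size(); ++r) {
      apply_mv(P, mv[r], fcc, o, lo, hi);
      double e2 = chain_energy(o, fcc, types, emat);
      evals += 1.0;
      if (e2 < E - 1e-12) { imp.push_back(o); impE.push_back(e2); }
    }
    if (imp.empty()) break;
    int pick = (int)(unif_rand() * imp.size());
    if (pick >= (int)imp.size()) pick = imp.size() - 1;
    P = imp[pick];
    E = impE[pick];
  }
  return List::create(_["coords"] = asMat(P), _["energy"] = E,
                      _["evals"] = evals);
}

static inline double ptdist(const Pt &a, const Pt &b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Population search: the elected best member proposes pull moves judged by
// Metropolis acceptance on the true energy under T_n = t0 * theta^n (n is
// the shared per-step counter); every other member proposes pull moves
// judged by the structural objective against the interval's frozen best
// snapshot. Every T steps all members are energy-evaluated and the best is
// re-elected. Terminates when an interval sees no SA-accepted move and the
// re-election keeps the same member, or at max_steps, or (optionally) when
// a target energy is reached.
//
// sof_mode 0: accept iff previous accepted move's sof >= proposed sof
//             (previous sof reset to +Inf at each interval start)
// sof_mode 1: accept iff the summed residue distance to the snapshot over
//             the affected range does not increase
// [[Rcpp::export]]
List cpp_search_loop(List pop, NumericVector energies0, int best0,
                     IntegerVector types, NumericMatrix emat, bool fcc,
                     int Tint, double t0, double theta, double max_steps,
                     int sof_mode, double target_energy) {
  int N = pop.size();
  std::vector<Chain> S(N);
  for (int i = 0; i < N; ++i) S[i] = asChain(pop[i]);
  std::vector<double> energies(energies0.begin(), energies0.end());
  int best = best0; // 0-based
  Chain snap = S[best];
  double curE = energies[best];

  double bestE = energies[0];
  int bi = 0;
  for (int i = 1; i < N; ++i)
    if (energies[i] < bestE) { bestE = energies[i]; bi = i; }
  Chain bestC = S[bi];

  bool haveTarget = !ISNA(target_energy);
  double steps = 0;
  long long intervals = 0;
  double e_evals = 0, s_evals = 0, r_evals = 0;
  std::vector<double> tr_energy;
  std::vector<int> tr_index, tr_sa;
  std::vector<double> sofprev(N);
  int terminated = -1; // 0 converged, 1 max_steps, 2 target
  if (haveTarget && bestE <= target_energy + 1e-9) terminated = 2;

  std::vector<Mv> mv;
  Chain o; int lo, hi;

  while (terminated < 0) {
    bool sa_acc = false;
    std::fill(sofprev.begin(), sofprev.end(), R_PosInf);
    int t = 0;
    for (; t < Tint; ++t) {
      if (steps >= max_steps) { terminated = 1; break; }
      double Tn = t0 * std::pow(theta, steps);
      // SA move for the elected member (one energy evaluation)
      enum_mvs(S[best], fcc, mv);
      e_evals += 1;
      if (!mv.empty()) {
        int id = (int)(unif_rand() * mv.size());
        if (id >= (int)mv.size()) id = mv.size() - 1;
        apply_mv(S[best], mv[id], fcc, o, lo, hi);
        double Ep = chain_energy(o, fcc, types, emat);
        double dE = Ep - curE;
        bool acc = (dE <= 0) ? true : (unif_rand() < std::exp(-dE / Tn));
        if (acc) {
          S[best] = o;
          curE = Ep;
          sa_acc = true;
          if (Ep < bestE) { bestE = Ep; bestC = o; }
        }
      }
      // structural moves for the rest (one structural evaluation each)
      for (int i = 0; i < N; ++i) {
        if (i == best) continue;
        enum_mvs(S[i], fcc, mv);
        s_evals += 1;
        if (mv.empty()) continue;
        int id = (int)(unif_rand() * mv.size());
        if (id >= (int)mv.size()) id = mv.size() - 1;
        apply_mv(S[i], mv[id], fcc, o, lo, hi);
        double sof = 0, sumOld = 0, sumNew = 0;
        for (int tt = lo; tt <= hi; ++tt) {
          double dOld = ptdist(S[i][tt], snap[tt]);
          double dNew = ptdist(o[tt], snap[tt]);
          sof += std::fabs(dOld - dNew);
          sumOld += dOld;
          sumNew += dNew;
        }
        sof /= (hi - lo + 1);
        bool acc = (sof_mode == 0) ? (sofprev[i] >= sof)
                                   : (sumNew <= sumOld + 1e-12);
        if (acc) {
          S[i] = o;
          if (sof_mode == 0) sofprev[i] = sof;
        }
      }
      steps += 1;
      if (haveTarget && bestE <= target_energy + 1e-9) {
        ++t;
        terminated = 2;
        break;
      }
    }
    if (t > 0) {
      // interval-end re-election (the elected member's energy is known)
      energies[best] = curE;
      for (int i = 0; i < N; ++i) {
        if (i == best) continue;
        energies[i] = chain_energy(S[i], fcc, types, emat);
        r_evals += 1;
        if (energies[i] < bestE) { bestE = energies[i]; bestC = S[i]; }
      }
      double mn = energies[0];
      for (int i = 1; i < N; ++i) if (energies[i] < mn) mn = energies[i];
      std::vector<int> mins;
      for (int i = 0; i < N; ++i)
        if (energies[i] <= mn + 1e-9) mins.push_back(i);
      int pick = (int)(unif_rand() * mins.size());
      if (pick >= (int)mins.size()) pick = mins.size() - 1;
      int nb = mins[pick];
      ++intervals;
      tr_energy.push_back(energies[nb]);
      tr_index.push_back(nb + 1);
      tr_sa.push_back(sa_acc ? 1 : 0);
      if (terminated < 0 && t == Tint && !sa_acc && nb == best)
        terminated = 0;
      best = nb;
      snap = S[best];
      curE = energies[best];
    }
    if (terminated >= 0) break;
  }

  // Decompose K = k*T + T' with 1 <= T' <= T (K = 0 only if terminated at init)
  double K = steps;
  double kc = 0, Tp = 0;
  if (K > 0) {
    double q = std::floor(K / Tint);
    double r = K - q * Tint;
    if (r == 0) { kc = q - 1; Tp = Tint; } else { kc = q; Tp = r; }
  }

  List popOut(N);
  for (int i = 0; i < N; ++i) popOut[i] = asMat(S[i]);
  return List::create(
    _["best_coords"] = asMat(bestC), _["best_energy"] = bestE,
    _["population"] = popOut,
    _["energies"] = NumericVector(energies.begin(), energies.end()),
    _["best_index"] = best + 1, _["steps"] = K, _["k"] = kc,
    _["t_prime"] = Tp, _["energy_evals"] = e_evals,
    _["structural_evals"] = s_evals, _["reelection_evals"] = r_evals,
    _["terminated"] = terminated,
    _["trace_energy"] = NumericVector(tr_energy.begin(), tr_energy.end()),
    _["trace_index"] = IntegerVector(tr_index.begin(), tr_index.end()),
    _["trace_sa"] = IntegerVector(tr_sa.begin(), tr_sa.end()));
}
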