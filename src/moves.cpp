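#include "pgmcmc.h"
#include <climits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Small helpers
// ---------------------------------------------------------------------------
static std::vector<char> component_edges(const Tree& t, int start) {
  std::vector<char> inC(t.nedges(), 0);
  std::vector<char> seen(t.nnodes(), 0);
  std::vector<int> st;
  st.push_back(start); seen[start] = 1;
  while (!st.empty()) {
    int n = st.back(); st.pop_back();
    for (int k = 0; k < t.deg[n]; ++k) {
      int e = t.adj[n][k];
      if (inC[e]) continue;
      inC[e] = 1;
      int m = t.other(e, n);
      if (!seen[m]) { seen[m] = 1; st.push_back(m); }
    }
  }
  return inC;
}

// BFS outward from edge b within its component: for every other edge, the
// endpoint through which it is first reached (`near`, the side facing b) and
// its node distance from b (adjacent edges are at distance 1).
static void bfs_from_edge(const Tree& t, int b,
                          std::vector<int>& near, std::vector<int>& dist) {
  near.assign(t.nedges(), -1);
  dist.assign(t.nedges(), INT_MAX);
  std::vector<int> nd(t.nnodes(), -1);
  std::vector<int> qu;
  dist[b] = 0;
  nd[t.eu[b]] = 0; nd[t.ev[b]] = 0;
  qu.push_back(t.eu[b]); qu.push_back(t.ev[b]);
  for (size_t h = 0; h < qu.size(); ++h) {
    int n = qu[h];
    for (int k = 0; k < t.deg[n]; ++k) {
      int e = t.adj[n][k];
      if (e == b || dist[e] != INT_MAX) continue;
      dist[e] = nd[n] + 1;
      near[e] = n;
      int m = t.other(e, n);
      if (nd[m] < 0) { nd[m] = nd[n] + 1; qu.push_back(m); }
    }
  }
}

static double lse(const std::vector<double>& lw, const std::vector<int>& idx, int excl) {
  double mx = -INFINITY;
  for (int i : idx) if (i != excl && lw[i] > mx) mx = lw[i];
  double s = 0;
  for (int i : idx) if (i != excl) s += std::exp(lw[i] - mx);
  return mx + std::log(s);
}

static int sample_logw(const std::vector<double>& lw, const std::vector<int>& idx,
                       int excl, RNG& rng) {
  double mx = -INFINITY;
  for (int i : idx) if (i != excl && lw[i] > mx) mx = lw[i];
  double tot = 0;
  for (int i : idx) if (i != excl) tot += std::exp(lw[i] - mx);
  double target = rng.u() * tot, acc = 0;
  int last = -1;
  for (int i : idx) {
    if (i == excl) continue;
    last = i;
    acc += std::exp(lw[i] - mx);
    if (acc >= target) return i;
  }
  return last;
}

// scale one branch with the multiplier proposal; returns log multiplier
static double scale_edge(Tree& t, int e, double lam, RNG& rng, Proposal& P) {
  double m = std::exp(lam * (rng.u() - 0.5));
  t.len[e] *= m;
  P.touched.push_back(e);
  return std::log(m);
}

// ---------------------------------------------------------------------------
// SPR pick: branch a, moving side ra (tip side forced for terminal branches),
// attachment node x, its two non-a edges.  Valid iff the remainder keeps at
// least three tips (equivalently, one of x's other neighbours is interior).
// ---------------------------------------------------------------------------
struct SprPick {
  bool ok = false;
  int a = -1, ra = -1, x = -1, e1 = -1, e2 = -1, f1 = -1, f2 = -1;
};

static SprPick spr_pick(const Tree& t, RNG& rng) {
  SprPick pk;
  for (int tries = 0; tries < 100000; ++tries) {
    int a = rng.ui(t.nedges());
    int u = t.eu[a], v = t.ev[a], ra;
    if (t.is_tip(u)) ra = u;
    else if (t.is_tip(v)) ra = v;
    else ra = (rng.u() < 0.5) ? u : v;
    int x = t.other(a, ra);
    int ee[2], c = 0;
    for (int k = 0; k < t.deg[x]; ++k) {
      int e = t.adj[x][k];
      if (e != a) ee[c++] = e;
    }
    int f1 = t.other(ee[0], x), f2 = t.other(ee[1], x);
    if (t.is_tip(f1) && t.is_tip(f2)) continue;  // remainder would have 2 tips
    pk.ok = true; pk.a = a; pk.ra = ra; pk.x = x;
    pk.e1 = ee[0]; pk.e2 = ee[1]; pk.f1 = f1; pk.f2 = f2;
    return pk;
  }
  return pk;
}

// prune: detach x (edges a and q inactive), bridge b spans x's two neighbours
static void spr_prune(Tree& t, int a, int x, int q, int b) {
  int fq = t.other(q, x), fb = t.other(b, x);
  t.act[a] = 0; t.act[q] = 0;
  t.eu[b] = fq; t.ev[b] = fb;
  t.build_adj();
}

// regraft x into edge r; the segment facing `near` takes identity q
static void spr_regraft(Tree& t, int x, int a, int q, int r, int near) {
  int farn = (t.eu[r] == near) ? t.ev[r] : t.eu[r];
  t.eu[q] = x; t.ev[q] = near; t.act[q] = 1;
  t.eu[r] = x; t.ev[r] = farn;
  t.act[a] = 1;
  t.build_adj();
}

// ---------------------------------------------------------------------------
// Stochastic NNI
// ---------------------------------------------------------------------------
Proposal propose_snni(Tree& t, RNG& rng) {
  Proposal P;
  int a = -1;
  for (int tries = 0; tries < 100000; ++tries) {
    int e = rng.ui(t.nedges());
    if (t.edge_internal(e)) { a = e; break; }
  }
  if (a < 0) return P;
  int x = t.eu[a], y = t.ev[a];
  int ex[2], ey[2], cx = 0, cy = 0;
  for (int k = 0; k < t.deg[x]; ++k) if (t.adj[x][k] != a) ex[cx++] = t.adj[x][k];
  for (int k = 0; k < t.deg[y]; ++k) if (t.adj[y][k] != a) ey[cy++] = t.adj[y][k];
  int eA = ex[0];
  int eC = (rng.u() < 0.5) ? ey[0] : ey[1];
  int rA = t.other(eA, x), rC = t.other(eC, y);
  t.eu[eA] = y; t.ev[eA] = rA;
  t.eu[eC] = x; t.ev[eC] = rC;
  t.build_adj();
  P.valid = true; P.logH = 0; P.logH_topo = 0; P.a = a;
  return P;
}

// ---------------------------------------------------------------------------
// Extension walk on the remainder, starting from bridge edge b.
// Returns the landing edge, its entry node, the step count and bookkeeping
// needed for the exact path-probability Hastings ratio.
// ---------------------------------------------------------------------------
struct WalkRes {
  int r = -1, entry = -1, s = 0;
  bool fwd_forced = false;       // stopped because the landing edge is terminal
  bool first_internal = false;
  int Ib = 0;                    // interior endpoints of the starting bridge
};

static WalkRes extension_walk(const Tree& t, int b, double pe, RNG& rng) {
  WalkRes w;
  int u = t.eu[b], v = t.ev[b];
  int cand[2], nc = 0;
  if (!t.is_tip(u)) cand[nc++] = u;
  if (!t.is_tip(v)) cand[nc++] = v;
  w.Ib = nc;
  if (nc == 0) return w;                    // no move possible
  int f = (nc == 1) ? cand[0] : cand[rng.ui(2)];
  // first step: one of f's edges other than b
  int ee[2], c = 0;
  for (int k = 0; k < t.deg[f]; ++k) if (t.adj[f][k] != b) ee[c++] = t.adj[f][k];
  int cur = ee[rng.ui(2)];
  int came = f;
  w.s = 1;
  int farn = t.other(cur, came);
  w.first_internal = !t.is_tip(farn);
  while (true) {
    if (t.is_tip(farn)) { w.fwd_forced = true; break; }
    if (rng.u() >= pe) break;               // stop with probability 1 - pe
    int nx[2], c2 = 0;
    for (int k = 0; k < t.deg[farn]; ++k)
      if (t.adj[farn][k] != cur) nx[c2++] = t.adj[farn][k];
    came = farn;
    cur = nx[rng.ui(2)];
    farn = t.other(cur, came);
    ++w.s;
  }
  w.r = cur; w.entry = came;
  return w;
}

// exact log proposal probability of a walk of s steps from a bridge with
// `Ib` interior endpoints, landing on an edge that is terminal (`forced`)
// or interior
static double walk_logq(int Ib, int s, bool forced, double pe) {
  return -std::log((double)Ib) - s * std::log(2.0) + (s - 1) * std::log(pe)
         + (forced ? 0.0 : std::log(1.0 - pe));
}

// ---------------------------------------------------------------------------
// eSPR
// ---------------------------------------------------------------------------
Proposal propose_espr(Tree& t, RNG& rng, const Tuning& tn) {
  Proposal P;
  SprPick pk = spr_pick(t, rng);
  if (!pk.ok) return P;
  // initial direction chosen among interior bridge endpoints; the pendant q
  // is the branch from x toward the walk
  int cand[2], nc = 0;
  if (!t.is_tip(pk.f1)) cand[nc++] = 1;
  if (!t.is_tip(pk.f2)) cand[nc++] = 2;
  int dir = (nc == 1) ? cand[0] : cand[rng.ui(2)];
  int q = (dir == 1) ? pk.e1 : pk.e2;
  int b = (dir == 1) ? pk.e2 : pk.e1;
  spr_prune(t, pk.a, pk.x, q, b);

  WalkRes w = extension_walk(t, b, tn.pe, rng);
  if (w.r < 0) { return P; }                // cannot happen for a valid pick
  int r = w.r;
  bool b_terminal = t.is_tip(t.eu[b]) || t.is_tip(t.ev[b]);
  int Ir = (!t.is_tip(t.eu[r])) + (!t.is_tip(t.ev[r]));
  double lqf = walk_logq(w.Ib, w.s, w.fwd_forced, tn.pe);
  double lqr = walk_logq(Ir, w.s, b_terminal, tn.pe);
  P.logH_topo = lqr - lqf;
  P.fwd_con = w.fwd_forced; P.rev_con = b_terminal;
  P.d1 = w.s; P.first_internal = w.first_internal;

  spr_regraft(t, pk.x, pk.a, q, r, w.entry);
  double lh = P.logH_topo;
  lh += scale_edge(t, pk.a, tn.lam_scale, rng, P);
  lh += scale_edge(t, q, tn.lam_scale, rng, P);
  lh += scale_edge(t, b, tn.lam_scale, rng, P);
  P.logH = lh;
  P.valid = true;
  P.a = pk.a; P.b = b; P.q = q; P.r = r;
  return P;
}

// ---------------------------------------------------------------------------
// eTBR
// ---------------------------------------------------------------------------
Proposal propose_etbr(Tree& t, RNG& rng, const Tuning& tn) {
  Proposal P;
  int a = -1, x[2], mov[2];
  for (int tries = 0; tries < 100000; ++tries) {
    int e = rng.ui(t.nedges());
    if (!t.edge_internal(e)) continue;
    int xs[2] = { t.eu[e], t.ev[e] };
    bool ok[2];
    for (int s = 0; s < 2; ++s) {
      int ee[2], c = 0;
      for (int k = 0; k < t.deg[xs[s]]; ++k)
        if (t.adj[xs[s]][k] != e) ee[c++] = t.adj[xs[s]][k];
      int h1 = t.other(ee[0], xs[s]), h2 = t.other(ee[1], xs[s]);
      ok[s] = !(t.is_tip(h1) && t.is_tip(h2));
    }
    if (!ok[0] && !ok[1]) continue;
    a = e; x[0] = xs[0]; x[1] = xs[1]; mov[0] = ok[0]; mov[1] = ok[1];
    break;
  }
  if (a < 0) return P;
  // forced end among movable ends; the other end moves with probability 1/2
  int forced;
  if (mov[0] && mov[1]) forced = rng.ui(2);
  else forced = mov[0] ? 0 : 1;
  bool moved[2];
  moved[forced] = true;
  int o = 1 - forced;
  moved[o] = mov[o] && (rng.u() < 0.5);

  t.act[a] = 0;
  t.build_adj();
  int qq[2] = { -1, -1 }, bb[2] = { -1, -1 }, rr[2] = { -1, -1 }, en[2] = { -1, -1 };
  double lh_topo = 0.0;
  bool first_int = true;
  int dd[2] = { 0, 0 };
  for (int s = 0; s < 2; ++s) {
    if (!moved[s]) continue;
    int ee[2], c = 0;
    for (int k = 0; k < t.deg[x[s]]; ++k) ee[c++] = t.adj[x[s]][k];
    int h1 = t.other(ee[0], x[s]), h2 = t.other(ee[1], x[s]);
    int cand[2], nc = 0;
    if (!t.is_tip(h1)) cand[nc++] = 1;
    if (!t.is_tip(h2)) cand[nc++] = 2;
    int dir = (nc == 1) ? cand[0] : cand[rng.ui(2)];
    int q = (dir == 1) ? ee[0] : ee[1];
    int b = (dir == 1) ? ee[1] : ee[0];
    int fq = t.other(q, x[s]), fb = t.other(b, x[s]);
    t.act[q] = 0;
    t.eu[b] = fq; t.ev[b] = fb;
    t.build_adj();
    WalkRes w = extension_walk(t, b, tn.pe, rng);
    bool b_terminal = t.is_tip(t.eu[b]) || t.is_tip(t.ev[b]);
    int Ir = (!t.is_tip(t.eu[w.r])) + (!t.is_tip(t.ev[w.r]));
    lh_topo += walk_logq(Ir, w.s, b_terminal, tn.pe)
             - walk_logq(w.Ib, w.s, w.fwd_forced, tn.pe);
    qq[s] = q; bb[s] = b; rr[s] = w.r; en[s] = w.entry;
    dd[s] = w.s;
    if (s == forced) first_int = w.first_internal;
  }
  for (int s = 0; s < 2; ++s) {
    if (!moved[s]) continue;
    spr_regraft(t, x[s], a, qq[s], rr[s], en[s]);
  }
  t.act[a] = 1;
  t.build_adj();
  double lh = lh_topo;
  P.touched.clear();
  lh += scale_edge(t, a, tn.lam_scale, rng, P);
  for (int s = 0; s < 2; ++s)
    if (moved[s]) lh += scale_edge(t, qq[s], tn.lam_scale, rng, P);
  P.valid = true;
  P.logH = lh; P.logH_topo = lh_topo;
  P.a = a;
  P.d1 = dd[forced]; P.d2 = dd[o]; P.moved2 = moved[o];
  P.other_movable = mov[o];
  P.first_internal = first_int;
  return P;
}

// ---------------------------------------------------------------------------
// pSPR (variants 1 and 2)
// ---------------------------------------------------------------------------
Proposal propose_pspr(Tree& t, const PatternData* guide, RNG& rng,
                      const Tuning& tn, int variant, bool hastings_on) {
  Proposal P;
  SprPick pk = spr_pick(t, rng);
  if (!pk.ok) return P;
  int q, b;
  if (rng.u() < 0.5) { q = pk.e1; b = pk.e2; }
  else { q = pk.e2; b = pk.e1; }
  spr_prune(t, pk.a, pk.x, q, b);

  int E = t.nedges();
  std::vector<double> logw(E, 0.0);
  std::vector<char> inC;
  if (guide && !guide->empty()) {
    std::vector<uint8_t> X, SA;
    edge_state_sets(t, t.eu[b], *guide, X, inC);
    fitch_component(t, pk.ra, *guide, &SA);
    int np = guide->npat;
    for (int e = 0; e < E; ++e) {
      if (!inC[e]) continue;
      double S = 0;
      const uint8_t* xe = &X[(size_t)e * np];
      for (int p = 0; p < np; ++p)
        if (!(xe[p] & SA[p])) S += guide->w[p];
      logw[e] = guide_logw(S, variant, tn, guide->N);
    }
  } else {
    inC = component_edges(t, t.eu[b]);
  }
  std::vector<int> cand;
  for (int e = 0; e < E; ++e) if (inC[e]) cand.push_back(e);

  int r = sample_logw(logw, cand, b, rng);
  std::vector<int> near, dist;
  bfs_from_edge(t, b, near, dist);
  double lf = logw[r] - lse(logw, cand, b);   // forward selection probability
  double lr = logw[b] - lse(logw, cand, r);   // reverse selection probability
  P.logH_topo = hastings_on ? (lr - lf) : 0.0;
  P.d1 = dist[r];

  spr_regraft(t, pk.x, pk.a, q, r, near[r]);
  double lh = P.logH_topo;
  lh += scale_edge(t, pk.a, tn.lam_scale, rng, P);
  lh += scale_edge(t, q, tn.lam_scale, rng, P);
  lh += scale_edge(t, b, tn.lam_scale, rng, P);
  P.logH = lh;
  P.valid = true;
  P.a = pk.a; P.b = b; P.q = q; P.r = r;
  return P;
}

// ---------------------------------------------------------------------------
// pTBR (variants 1 and 2)
// ---------------------------------------------------------------------------
Proposal propose_ptbr(Tree& t, const PatternData* guide, RNG& rng,
                      const Tuning& tn, int variant, bool hastings_on) {
  Proposal P;
  int E = t.nedges();
  int np = (guide && !guide->empty()) ? guide->npat : 0;
  for (int tries = 0; tries < 100000; ++tries) {
    int a = -1;
    {
      int e = rng.ui(E);
      if (!t.edge_internal(e)) continue;
      a = e;
    }
    int x1 = t.eu[a], x2 = t.ev[a];
    // snapshot for rollback if the pick admits no non-identity pair
    std::vector<int> eu0 = t.eu, ev0 = t.ev;
    std::vector<char> act0 = t.act;

    t.act[a] = 0;
    int xx[2] = { x1, x2 };
    int qq[2], bb[2], origfar[2];
    for (int s = 0; s < 2; ++s) {
      int ee[2], c = 0;
      t.build_adj();
      for (int k = 0; k < t.deg[xx[s]]; ++k) ee[c++] = t.adj[xx[s]][k];
      int qs, bs;
      if (rng.u() < 0.5) { qs = ee[0]; bs = ee[1]; }
      else { qs = ee[1]; bs = ee[0]; }
      int fq = t.other(qs, xx[s]), fb = t.other(bs, xx[s]);
      t.act[qs] = 0;
      t.eu[bs] = fq; t.ev[bs] = fb;
      qq[s] = qs; bb[s] = bs; origfar[s] = fq;
    }
    t.build_adj();

    // candidate edges within delta of each bridge
    std::vector<int> near1, dist1, near2, dist2;
    bfs_from_edge(t, bb[0], near1, dist1);
    bfs_from_edge(t, bb[1], near2, dist2);
    std::vector<char> in1 = component_edges(t, t.eu[bb[0]]);
    std::vector<char> in2 = component_edges(t, t.eu[bb[1]]);
    std::vector<int> C1, C2;
    for (int e = 0; e < E; ++e) {
      if (in1[e] && (e == bb[0] || dist1[e] <= tn.delta)) C1.push_back(e);
      if (in2[e] && (e == bb[1] || dist2[e] <= tn.delta)) C2.push_back(e);
    }
    if ((int)C1.size() * (int)C2.size() < 2) {
      t.eu = eu0; t.ev = ev0; t.act = act0; t.build_adj();
      continue;                              // only the identity pair exists
    }

    // parsimony scores for candidate pairs from per-edge Fitch sets
    std::vector<uint8_t> X1, X2;
    std::vector<char> dum;
    if (np) {
      edge_state_sets(t, t.eu[bb[0]], *guide, X1, dum);
      edge_state_sets(t, t.eu[bb[1]], *guide, X2, dum);
    }
    auto pair_logw = [&](int i, int j) {
      if (!np) return 0.0;
      double S = 0;
      const uint8_t* xi = &X1[(size_t)i * np];
      const uint8_t* xj = &X2[(size_t)j * np];
      for (int p = 0; p < np; ++p)
        if (!(xi[p] & xj[p])) S += guide->w[p];
      return guide_logw(S, variant, tn, guide->N);
    };

    int m1 = C1.size(), m2 = C2.size();
    std::vector<double> lw((size_t)m1 * m2);
    int idb = -1;
    for (int i = 0; i < m1; ++i)
      for (int j = 0; j < m2; ++j) {
        lw[(size_t)i * m2 + j] = pair_logw(C1[i], C2[j]);
        if (C1[i] == bb[0] && C2[j] == bb[1]) idb = i * m2 + j;
      }
    std::vector<int> allp(m1 * m2);
    for (int i = 0; i < m1 * m2; ++i) allp[i] = i;
    int pick = sample_logw(lw, allp, idb, rng);
    int r1 = C1[pick / m2], r2 = C2[pick % m2];
    double lf = lw[pick] - lse(lw, allp, idb);

    // reverse neighbourhood: candidates within delta of the landing edges
    std::vector<int> nr1, dr1, nr2, dr2;
    bfs_from_edge(t, r1, nr1, dr1);
    bfs_from_edge(t, r2, nr2, dr2);
    std::vector<int> C1r, C2r;
    for (int e = 0; e < E; ++e) {
      if (in1[e] && (e == r1 || dr1[e] <= tn.delta)) C1r.push_back(e);
      if (in2[e] && (e == r2 || dr2[e] <= tn.delta)) C2r.push_back(e);
    }
    int m1r = C1r.size(), m2r = C2r.size();
    std::vector<double> lwr((size_t)m1r * m2r);
    int idr = -1, idbrev = -1;
    for (int i = 0; i < m1r; ++i)
      for (int j = 0; j < m2r; ++j) {
        lwr[(size_t)i * m2r + j] = pair_logw(C1r[i], C2r[j]);
        if (C1r[i] == r1 && C2r[j] == r2) idr = i * m2r + j;
        if (C1r[i] == bb[0] && C2r[j] == bb[1]) idbrev = i * m2r + j;
      }
    std::vector<int> allr(m1r * m2r);
    for (int i = 0; i < m1r * m2r; ++i) allr[i] = i;
    double lrv = lwr[idbrev] - lse(lwr, allr, idr);
    P.logH_topo = hastings_on ? (lrv - lf) : 0.0;

    // reconnect both ends
    int rr[2] = { r1, r2 };
    for (int s = 0; s < 2; ++s) {
      int nearn;
      if (rr[s] == bb[s]) nearn = origfar[s];
      else nearn = (s == 0) ? near1[rr[s]] : near2[rr[s]];
      spr_regraft(t, xx[s], a, qq[s], rr[s], nearn);
    }
    t.act[a] = 1;
    t.build_adj();
    double lh = P.logH_topo;
    lh += scale_edge(t, a, tn.lam_scale, rng, P);
    lh += scale_edge(t, qq[0], tn.lam_scale, rng, P);
    lh += scale_edge(t, qq[1], tn.lam_scale, rng, P);
    P.logH = lh;
    P.valid = true;
    P.a = a; P.b = bb[0]; P.q = qq[0]; P.r = r1;
    P.d1 = (r1 == bb[0]) ? 0 : dist1[r1];
    P.d2 = (r2 == bb[1]) ? 0 : dist2[r2];
    return P;
  }
  return P;
}

Proposal propose_tree_move(int move, Tree& t, const PatternData* guide,
                           RNG& rng, const Tuning& tn, bool hastings_on) {
  switch (move) {
    case MV_SNNI:  return propose_snni(t, rng);
    case MV_ESPR:  return propose_espr(t, rng, tn);
    case MV_ETBR:  return propose_etbr(t, rng, tn);
    case MV_PSPR1: return propose_pspr(t, guide, rng, tn, 1, hastings_on);
    case MV_PSPR2: return propose_pspr(t, guide, rng, tn, 2, hastings_on);
    case MV_PTBR1: return propose_ptbr(t, guide, rng, tn, 1, hastings_on);
    case MV_PTBR2: return propose_ptbr(t, guide, rng, tn, 2, hastings_on);
    default: stop("not a tree move");
  }
}

// ---------------------------------------------------------------------------
// Exports
// ---------------------------------------------------------------------------
Tuning tuning_from_R(List tl) {
  Tuning tn;
  if (tl.containsElementNamed("pe")) tn.pe = as<double>(tl["pe"]);
  if (tl.containsElementNamed("eps1")) tn.eps1 = as<double>(tl["eps1"]);
  if (tl.containsElementNamed("eps2")) tn.eps2 = as<double>(tl["eps2"]);
  if (tl.containsElementNamed("eta")) tn.eta = as<double>(tl["eta"]);
  if (tl.containsElementNamed("rho_factor")) tn.rho_factor = as<double>(tl["rho_factor"]);
  if (tl.containsElementNamed("delta")) tn.delta = as<int>(tl["delta"]);
  if (tl.containsElementNamed("lam_scale")) tn.lam_scale = as<double>(tl["lam_scale"]);
  if (tl.containsElementNamed("lam_brlen")) tn.lam_brlen = as<double>(tl["lam_brlen"]);
  if (tl.containsElementNamed("lam_tl")) tn.lam_tl = as<double>(tl["lam_tl"]);
  return tn;
}

// [[Rcpp::export]]
NumericVector cpp_guide_logw(NumericVector S, int variant, List tuning, double N) {
  Tuning tn = tuning_from_R(tuning);
  NumericVector out(S.size());
  for (int i = 0; i < S.size(); ++i) out[i] = guide_logw(S[i], variant, tn, N);
  return out;
}

// Incremental parsimony scores for all SPR regraft candidates.
// a, aside, pendant are 1-based ids; pendant = 0 picks the lower edge id.
// [[Rcpp::export]]
List cpp_regraft_scores(int ntips, IntegerMatrix edge, List data,
                        int a, int aside, int pendant) {
  NumericVector len(edge.nrow(), 0.1);
  Tree t = tree_from_R(ntips, edge, len);
  PatternData d = patterns_from_R(data);
  a -= 1;
  int ra = aside - 1;
  if (a < 0 || a >= t.nedges()) stop("branch id out of range");
  if (t.eu[a] != ra && t.ev[a] != ra) stop("aside is not an endpoint of a");
  int x = t.other(a, ra);
  if (t.is_tip(x)) stop("moving side must leave an interior attachment node");
  int ee[2], c = 0;
  for (int k = 0; k < t.deg[x]; ++k) if (t.adj[x][k] != a) ee[c++] = t.adj[x][k];
  int f1 = t.other(ee[0], x), f2 = t.other(ee[1], x);
  if (t.is_tip(f1) && t.is_tip(f2)) stop("no valid regraft candidates (remainder too small)");
  int q, b;
  if (pendant == 0) { q = std::min(ee[0], ee[1]); b = std::max(ee[0], ee[1]); }
  else {
    q = pendant - 1;
    if (q != ee[0] && q != ee[1]) stop("pendant must be one of the attachment node's edges");
    b = (q == ee[0]) ? ee[1] : ee[0];
  }
  double f_orig = fitch_component(t, 0, d);
  spr_prune(t, a, x, q, b);
  std::vector<uint8_t> X, SA;
  std::vector<char> inC;
  edge_state_sets(t, t.eu[b], d, X, inC);
  double fA = fitch_component(t, ra, d, &SA);
  double fR = fitch_component(t, t.eu[b], d);
  int np = d.npat;
  std::vector<int> cid;
  std::vector<double> sc;
  for (int e = 0; e < t.nedges(); ++e) {
    if (!inC[e]) continue;
    double S = 0;
    const uint8_t* xe = &X[(size_t)e * np];
    for (int p = 0; p < np; ++p) if (!(xe[p] & SA[p])) S += d.w[p];
    cid.push_back(e + 1);
    sc.push_back(S);
  }
  // remainder edges for verification by the caller
  IntegerMatrix rem((int)cid.size(), 2);
  NumericVector rlen((int)cid.size());
  for (size_t i = 0; i < cid.size(); ++i) {
    int e = cid[i] - 1;
    rem(i, 0) = t.eu[e] + 1; rem(i, 1) = t.ev[e] + 1;
    rlen[i] = t.len[e];
  }
  return List::create(_["bridge"] = b + 1, _["pendant"] = q + 1,
                      _["candidates"] = wrap(cid), _["scores"] = wrap(sc),
                      _["fitch_original"] = f_orig,
                      _["fitch_moving"] = fA, _["fitch_remainder"] = fR,
                      _["remainder_edge"] = rem, _["remainder_length"] = rlen);
}

// Incremental parsimony scores for TBR reconnection pairs within delta.
// [[Rcpp::export]]
List cpp_bisect_scores(int ntips, IntegerMatrix edge, List data,
                       int a, int delta) {
  NumericVector len(edge.nrow(), 0.1);
  Tree t = tree_from_R(ntips, edge, len);
  PatternData d = patterns_from_R(data);
  a -= 1;
  if (a < 0 || a >= t.nedges()) stop("branch id out of range");
  if (!t.edge_internal(a)) stop("TBR requires an interior branch");
  if (delta < 1) stop("delta must be >= 1");
  int xx[2] = { t.eu[a], t.ev[a] };
  t.act[a] = 0;
  int qq[2], bb[2];
  for (int s = 0; s < 2; ++s) {
    t.build_adj();
    int ee[2], c = 0;
    for (int k = 0; k < t.deg[xx[s]]; ++k) ee[c++] = t.adj[xx[s]][k];
    int q = std::min(ee[0], ee[1]), b = std::max(ee[0], ee[1]);
    int fq = t.other(q, xx[s]), fb = t.other(b, xx[s]);
    t.act[q] = 0;
    t.eu[b] = fq; t.ev[b] = fb;
    qq[s] = q; bb[s] = b;
  }
  t.build_adj();
  std::vector<int> near1, dist1, near2, dist2;
  bfs_from_edge(t, bb[0], near1, dist1);
  bfs_from_edge(t, bb[1], near2, dist2);
  std::vector<char> in1 = component_edges(t, t.eu[bb[0]]);
  std::vector<char> in2 = component_edges(t, t.eu[bb[1]]);
  std::vector<int> C1, C2, D1, D2;
  for (int e = 0; e < t.nedges(); ++e) {
    if (in1[e] && (e == bb[0] || dist1[e] <= delta)) { C1.push_back(e); D1.push_back(e == bb[0] ? 0 : dist1[e]); }
    if (in2[e] && (e == bb[1] || dist2[e] <= delta)) { C2.push_back(e); D2.push_back(e == bb[1] ? 0 : dist2[e]); }
  }
  std::vector<uint8_t> X1, X2;
  std::vector<char> dum;
  edge_state_sets(t, t.eu[bb[0]], d, X1, dum);
  edge_state_sets(t, t.eu[bb[1]], d, X2, dum);
  double f1 = fitch_component(t, t.eu[bb[0]], d);
  double f2 = fitch_component(t, t.eu[bb[1]], d);
  int np = d.npat;
  NumericMatrix S((int)C1.size(), (int)C2.size());
  for (size_t i = 0; i < C1.size(); ++i)
    for (size_t j = 0; j < C2.size(); ++j) {
      double s = 0;
      const uint8_t* xi = &X1[(size_t)C1[i] * np];
      const uint8_t* xj = &X2[(size_t)C2[j] * np];
      for (int p = 0; p < np; ++p) if (!(xi[p] & xj[p])) s += d.w[p];
      S(i, j) = s;
    }
  IntegerVector c1(C1.size()), c2(C2.size());
  for (size_t i = 0; i < C1.size(); ++i) c1[i] = C1[i] + 1;
  for (size_t j = 0; j < C2.size(); ++j) c2[j] = C2[j] + 1;
  return List::create(_["bridge1"] = bb[0] + 1, _["bridge2"] = bb[1] + 1,
                      _["pendant1"] = qq[0] + 1, _["pendant2"] = qq[1] + 1,
                      _["candidates1"] = c1, _["candidates2"] = c2,
                      _["dist1"] = wrap(D1), _["dist2"] = wrap(D2),
                      _["scores"] = S,
                      _["fitch_side1"] = f1, _["fitch_side2"] = f2);
}

// Draw independent proposals from the same starting tree (for tests).
// [[Rcpp::export]]
List cpp_propose_batch(int ntips, IntegerMatrix edge, NumericVector len,
                       int move, List tuning, Nullable<List> guide,
                       double seed, int nrep, int keep) {
  Tree t0 = tree_from_R(ntips, edge, len);
  Tuning tn = tuning_from_R(tuning);
  PatternData gd;
  bool has_guide = false;
  if (guide.isNotNull()) { gd = patterns_from_R(guide.get()); has_guide = true; }
  RNG rng((uint64_t)seed);
  NumericVector logH(nrep), logHt(nrep);
  IntegerVector d1(nrep), d2(nrep), aa(nrep), bb(nrep), qq(nrep), rr(nrep);
  LogicalVector mv2(nrep), fint(nrep), fcon(nrep), rcon(nrep), omv(nrep);
  List trees(keep);
  for (int i = 0; i < nrep; ++i) {
    Tree t = t0;
    Proposal P = propose_tree_move(move, t, has_guide ? &gd : nullptr, rng, tn, true);
    if (!P.valid) stop("move inapplicable to this tree");
    logH[i] = P.logH; logHt[i] = P.logH_topo;
    d1[i] = P.d1; d2[i] = P.d2;
    aa[i] = P.a + 1; bb[i] = P.b + 1; qq[i] = P.q + 1; rr[i] = P.r + 1;
    mv2[i] = P.moved2; fint[i] = P.first_internal; omv[i] = P.other_movable;
    fcon[i] = P.fwd_con; rcon[i] = P.rev_con;
    if (i < keep) trees[i] = tree_to_R(t);
  }
  return List::create(_["logH"] = logH, _["logH_topo"] = logHt,
                      _["d1"] = d1, _["d2"] = d2, _["moved2"] = mv2,
                      _["first_internal"] = fint, _["other_movable"] = omv,
                      _["fwd_constrained"] = fcon, _["rev_constrained"] = rcon,
                      _["a"] = aa, _["b"] = bb, _["q"] = qq, _["r"] = rr,
                      _["trees"] = trees);
}
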