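#include "pgmcmc.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Construction / export
// ---------------------------------------------------------------------------
Tree tree_from_R(int ntips, const IntegerMatrix& edge, const NumericVector& len) {
  Tree t;
  t.nt = ntips;
  int E = edge.nrow();
  if (E != 2 * ntips - 3) stop("expected %d edges for %d tips, got %d",
                               2 * ntips - 3, ntips, E);
  t.eu.resize(E); t.ev.resize(E);
  t.len.resize(E); t.act.assign(E, 1);
  for (int e = 0; e < E; ++e) {
    t.eu[e] = edge(e, 0) - 1;
    t.ev[e] = edge(e, 1) - 1;
    t.len[e] = len[e];
    if (t.eu[e] < 0 || t.eu[e] >= t.nnodes() || t.ev[e] < 0 || t.ev[e] >= t.nnodes())
      stop("edge endpoint out of range");
  }
  t.build_adj();
  for (int n = 0; n < t.nnodes(); ++n) {
    int want = t.is_tip(n) ? 1 : 3;
    if (t.deg[n] != want) stop("node %d has degree %d (expected %d)",
                               n + 1, t.deg[n], want);
  }
  return t;
}

List tree_to_R(const Tree& t) {
  int E = t.nedges();
  IntegerMatrix edge(E, 2);
  NumericVector len(E);
  for (int e = 0; e < E; ++e) {
    edge(e, 0) = t.eu[e] + 1;
    edge(e, 1) = t.ev[e] + 1;
    len[e] = t.len[e];
  }
  return List::create(_["ntips"] = t.nt, _["edge"] = edge, _["length"] = len);
}

static void newick_sub(const Tree& t, int node, int from_edge,
                       const std::vector<std::string>& lab, std::string& out) {
  if (t.is_tip(node)) {
    out += lab[node];
  } else {
    out += "(";
    bool first = true;
    for (int k = 0; k < t.deg[node]; ++k) {
      int e = t.adj[node][k];
      if (e == from_edge) continue;
      if (!first) out += ",";
      first = false;
      newick_sub(t, t.other(e, node), e, lab, out);
      char buf[40];
      snprintf(buf, sizeof(buf), ":%.10g", t.len[e]);
      out += buf;
    }
    out += ")";
  }
}

std::string tree_newick(const Tree& t, const std::vector<std::string>& lab) {
  // root the written form at the internal node adjacent to tip 0
  int h = t.other(t.adj[0][0], 0);
  std::string out;
  out += "(";
  for (int k = 0; k < t.deg[h]; ++k) {
    int e = t.adj[h][k];
    if (k > 0) out += ",";
    newick_sub(t, t.other(e, h), e, lab, out);
    char buf[40];
    snprintf(buf, sizeof(buf), ":%.10g", t.len[e]);
    out += buf;
  }
  out += ");";
  return out;
}

std::vector<uint32_t> tree_splits(const Tree& t) {
  if (t.nt > 31) stop("split masks support at most 31 tips");
  // tip mask below each directed edge via one postorder pass from node 0
  std::vector<uint32_t> below(t.nedges(), 0);
  // iterative postorder rooted at tip 0
  std::vector<int> stack_node, stack_edge, order_node, order_edge;
  stack_node.push_back(t.other(t.adj[0][0], 0));
  stack_edge.push_back(t.adj[0][0]);
  std::vector<char> seen(t.nnodes(), 0);
  seen[0] = 1;
  while (!stack_node.empty()) {
    int n = stack_node.back(); stack_node.pop_back();
    int pe = stack_edge.back(); stack_edge.pop_back();
    seen[n] = 1;
    order_node.push_back(n); order_edge.push_back(pe);
    for (int k = 0; k < t.deg[n]; ++k) {
      int e = t.adj[n][k];
      if (e == pe) continue;
      stack_node.push_back(t.other(e, n));
      stack_edge.push_back(e);
    }
  }
  for (int i = (int)order_node.size() - 1; i >= 0; --i) {
    int n = order_node[i], pe = order_edge[i];
    uint32_t m = 0;
    if (t.is_tip(n)) m = 1u << n;
    else for (int k = 0; k < t.deg[n]; ++k) {
      int e = t.adj[n][k];
      if (e != pe) m |= below[e];
    }
    below[pe] = m;
  }
  std::vector<uint32_t> out;
  uint32_t all = (t.nt == 31) ? 0x7fffffffu : ((1u << t.nt) - 1u);
  for (int e = 0; e < t.nedges(); ++e) {
    if (!t.act[e] || !t.edge_internal(e)) continue;
    uint32_t m = below[e];
    if (m & 1u) m = all & ~m;       // canonical side excludes tip 0
    out.push_back(m);
  }
  std::sort(out.begin(), out.end());
  return out;
}

// ---------------------------------------------------------------------------
// Pattern data
// ---------------------------------------------------------------------------
PatternData patterns_from_R(List d) {
  PatternData p;
  IntegerMatrix st = d["states"];
  NumericVector w = d["weights"];
  p.ntax = st.nrow();
  p.npat = st.ncol();
  p.N = d.containsElementNamed("nsites") ? as<double>(d["nsites"]) : sum(w);
  p.st.resize((size_t)p.ntax * p.npat);
  for (int i = 0; i < p.ntax; ++i)
    for (int j = 0; j < p.npat; ++j) {
      int s = st(i, j);
      if (s < 1 || s > 15) stop("state bitmask out of range");
      p.st[(size_t)i * p.npat + j] = (uint8_t)s;
    }
  p.w.assign(w.begin(), w.end());
  return p;
}

// ---------------------------------------------------------------------------
// Fitch parsimony
// ---------------------------------------------------------------------------
// Postorder node/edge lists for the component containing `start`, rooted there.
static void component_postorder(const Tree& t, int start,
                                std::vector<int>& nodes, std::vector<int>& pedge) {
  nodes.clear(); pedge.clear();
  std::vector<int> sn, se;
  sn.push_back(start); se.push_back(-1);
  while (!sn.empty()) {
    int n = sn.back(); sn.pop_back();
    int pe = se.back(); se.pop_back();
    nodes.push_back(n); pedge.push_back(pe);
    for (int k = 0; k < t.deg[n]; ++k) {
      int e = t.adj[n][k];
      if (e == pe) continue;
      sn.push_back(t.other(e, n));
      se.push_back(e);
    }
  }
  // preorder recorded; reverse for postorder
  std::reverse(nodes.begin(), nodes.end());
  std::reverse(pedge.begin(), pedge.end());
}

double fitch_component(const Tree& t, int start, const PatternData& d,
                       std::vector<uint8_t>* rootset) {
  std::vector<int> nodes, pedge;
  component_postorder(t, start, nodes, pedge);
  int np = d.npat;
  std::vector<uint8_t> set((size_t)t.nnodes() * np, 0);
  double total = 0.0;
  for (size_t i = 0; i < nodes.size(); ++i) {
    int n = nodes[i];
    uint8_t* sn = &set[(size_t)n * np];
    std::vector<char> started(np, 0);
    if (t.is_tip(n)) {
      for (int p = 0; p < np; ++p) { sn[p] = d.st[(size_t)n * np + p]; started[p] = 1; }
    }
    for (int k = 0; k < t.deg[n]; ++k) {
      int e = t.adj[n][k];
      if (e == pedge[i]) continue;
      const uint8_t* sc = &set[(size_t)t.other(e, n) * np];
      for (int p = 0; p < np; ++p) {
        if (!started[p]) { sn[p] = sc[p]; started[p] = 1; continue; }
        uint8_t x = sn[p] & sc[p];
        if (x) sn[p] = x;
        else { sn[p] = sn[p] | sc[p]; total += d.w[p]; }
      }
    }
  }
  if (rootset) {
    rootset->assign(np, 0);
    const uint8_t* sr = &set[(size_t)start * np];
    std::copy(sr, sr + np, rootset->begin());
  }
  return total;
}

void edge_state_sets(const Tree& t, int start, const PatternData& d,
                     std::vector<uint8_t>& X, std::vector<char>& inC) {
  int np = d.npat, E = t.nedges();
  std::vector<int> nodes, pedge;
  component_postorder(t, start, nodes, pedge);
  inC.assign(E, 0);
  for (size_t i = 0; i < nodes.size(); ++i)
    if (pedge[i] >= 0) inC[pedge[i]] = 1;
  // down[e]: set of the subtree on the far side of e (away from start)
  std::vector<uint8_t> down((size_t)E * np, 0), up((size_t)E * np, 0);
  std::vector<uint8_t> tmp((size_t)t.nnodes() * np, 0);
  for (size_t i = 0; i < nodes.size(); ++i) {
    int n = nodes[i];
    uint8_t* sn = &tmp[(size_t)n * np];
    std::vector<char> started(np, 0);
    if (t.is_tip(n)) {
      for (int p = 0; p < np; ++p) { sn[p] = d.st[(size_t)n * np + p]; started[p] = 1; }
    }
    for (int k = 0; k < t.deg[n]; ++k) {
      int e = t.adj[n][k];
      if (e == pedge[i]) continue;
      const uint8_t* sc = &down[(size_t)e * np];
      for (int p = 0; p < np; ++p) {
        if (!started[p]) { sn[p] = sc[p]; started[p] = 1; continue; }
        uint8_t x = sn[p] & sc[p];
        sn[p] = x ? x : (uint8_t)(sn[p] | sc[p]);
      }
    }
    if (pedge[i] >= 0) {
      uint8_t* de = &down[(size_t)pedge[i] * np];
      std::copy(sn, sn + np, de);
    }
  }
  // preorder (reverse of postorder): up[e] = set of the start-side of e,
  // i.e. Fitch combine at the near node of: its tip state (if tip), up of
  // its parent edge, and down of its other child edges.
  for (int i = (int)nodes.size() - 1; i >= 0; --i) {
    int n = nodes[i];
    for (int k = 0; k < t.deg[n]; ++k) {
      int e = t.adj[n][k];
      if (e == pedge[i]) continue;
      uint8_t* ue = &up[(size_t)e * np];
      std::vector<char> started(np, 0);
      if (t.is_tip(n)) {
        for (int p = 0; p < np; ++p) { ue[p] = d.st[(size_t)n * np + p]; started[p] = 1; }
      }
      if (pedge[i] >= 0) {
        const uint8_t* pu = &up[(size_t)pedge[i] * np];
        for (int p = 0; p < np; ++p) {
          if (!started[p]) { ue[p] = pu[p]; started[p] = 1; continue; }
          uint8_t x = ue[p] & pu[p];
          ue[p] = x ? x : (uint8_t)(ue[p] | pu[p]);
        }
      }
      for (int k2 = 0; k2 < t.deg[n]; ++k2) {
        int e2 = t.adj[n][k2];
        if (e2 == e || e2 == pedge[i]) continue;
        const uint8_t* dc = &down[(size_t)e2 * np];
        for (int p = 0; p < np; ++p) {
          if (!started[p]) { ue[p] = dc[p]; started[p] = 1; continue; }
          uint8_t x = ue[p] & dc[p];
          ue[p] = x ? x : (uint8_t)(ue[p] | dc[p]);
        }
      }
    }
  }
  if ((int)X.size() != E * np) X.assign((size_t)E * np, 0);
  for (int e = 0; e < E; ++e) {
    if (!inC[e]) continue;
    const uint8_t* de = &down[(size_t)e * np];
    const uint8_t* ue = &up[(size_t)e * np];
    uint8_t* xe = &X[(size_t)e * np];
    for (int p = 0; p < np; ++p) {
      uint8_t x = de[p] & ue[p];
      xe[p] = x ? x : (uint8_t)(de[p] | ue[p]);
    }
  }
}

// ---------------------------------------------------------------------------
// Exported helpers for the R layer and the test suite
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_fitch(int ntips, IntegerMatrix edge, List data) {
  NumericVector len(edge.nrow(), 0.1);
  Tree t = tree_from_R(ntips, edge, len);
  PatternData d = patterns_from_R(data);
  if (d.ntax != ntips) stop("data/tree taxon count mismatch");
  return fitch_component(t, 0, d);
}

// [[Rcpp::export]]
CharacterVector cpp_newick(int ntips, IntegerMatrix edge, NumericVector len,
                           CharacterVector labels) {
  Tree t = tree_from_R(ntips, edge, len);
  std::vector<std::string> lab(ntips);
  for (int i = 0; i < ntips; ++i) lab[i] = as<std::string>(labels[i]);
  return CharacterVector::create(tree_newick(t, lab));
}

// [[Rcpp::export]]
IntegerVector cpp_splits(int ntips, IntegerMatrix edge) {
  NumericVector len(edge.nrow(), 0.1);
  Tree t = tree_from_R(ntips, edge, len);
  std::vector<uint32_t> s = tree_splits(t);
  IntegerVector out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = (int)s[i];
  return out;
}
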