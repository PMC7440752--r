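#ifndef PGMCMC_H
#define PGMCMC_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <string>
#include <cmath>
#include <random>

// ---------------------------------------------------------------------------
// Deterministic RNG (explicit bit mapping so streams are platform-stable)
// ---------------------------------------------------------------------------
struct RNG {
  std::mt19937_64 g;
  explicit RNG(uint64_t seed) : g(seed) {}
  double u() { return (g() >> 11) * (1.0 / 9007199254740992.0); } // [0,1)
  int ui(int n) { return (int)(u() * n) % n; }                    // 0..n-1
};

// ---------------------------------------------------------------------------
// Site-pattern data: bitmask states over {A=1,C=2,G=4,T=8}, weighted patterns
// ---------------------------------------------------------------------------
struct PatternData {
  int ntax = 0, npat = 0;
  double N = 0;                  // total sites (sum of weights)
  std::vector<uint8_t> st;       // ntax * npat, taxon-major: st[tax*npat + p]
  std::vector<double> w;         // pattern weights
  bool empty() const { return npat == 0; }
};

PatternData patterns_from_R(Rcpp::List d);

// ---------------------------------------------------------------------------
// Unrooted binary tree with stable edge identifiers.
// Nodes: 0..nt-1 tips, nt..2nt-3 internal. Edges are id-indexed; surgery
// reassigns endpoints but never ids, so branch lengths travel with ids.
// ---------------------------------------------------------------------------
struct Tree {
  int nt = 0;
  std::vector<int> eu, ev;       // endpoints per edge id
  std::vector<double> len;
  std::vector<char> act;         // active flag (pruned edges are inactive)
  std::vector<std::array<int,3>> adj; // node -> incident active edge ids
  std::vector<int> deg;

  int nedges() const { return (int)eu.size(); }
  int nnodes() const { return 2 * nt - 2; }
  bool is_tip(int n) const { return n < nt; }
  int other(int e, int n) const { return eu[e] == n ? ev[e] : eu[e]; }

  void build_adj() {
    adj.assign(nnodes(), {{-1,-1,-1}});
    deg.assign(nnodes(), 0);
    for (int e = 0; e < nedges(); ++e) {
      if (!act[e]) continue;
      adj[eu[e]][deg[eu[e]]++] = e;
      adj[ev[e]][deg[ev[e]]++] = e;
    }
  }
  bool edge_internal(int e) const { return !is_tip(eu[e]) && !is_tip(ev[e]); }
};

Tree tree_from_R(int ntips, const Rcpp::IntegerMatrix& edge,
                 const Rcpp::NumericVector& len);
Rcpp::List tree_to_R(const Tree& t);
std::string tree_newick(const Tree& t, const std::vector<std::string>& labels);

// Splits of internal edges as tip bitmasks (side not containing tip 0),
// valid for nt <= 31; returns sorted masks.
std::vector<uint32_t> tree_splits(const Tree& t);

// ---------------------------------------------------------------------------
// Fitch parsimony
// ---------------------------------------------------------------------------
// Weighted Fitch score of the connected component containing `start`.
// If rootset != NULL it receives the preliminary state set at `start`
// (one uint8_t per pattern).
double fitch_component(const Tree& t, int start, const PatternData& d,
                       std::vector<uint8_t>* rootset = nullptr);

// For every active edge in the component containing `start`, the Fitch set
// of the edge viewed as a root position (combine of the two directed subtree
// sets).  X is indexed [edge id * npat + p]; `inC` flags component edges.
void edge_state_sets(const Tree& t, int start, const PatternData& d,
                     std::vector<uint8_t>& X, std::vector<char>& inC);

// ---------------------------------------------------------------------------
// Move machinery
// ---------------------------------------------------------------------------
struct Tuning {
  double pe = 0.5;
  double eps1 = 0.5, eps2 = 0.1;
  double eta = 1e-4;
  double rho_factor = 0.25;      // 1/4 default; 3/4 available
  int    delta = 5;
  double lam_scale = 2.0 * std::log(1.05); // branch scalers inside tree moves
  double lam_brlen = 2.0 * std::log(2.0);  // standalone branch-length scaler
  double lam_tl    = 2.0 * std::log(1.1);  // tree-length multiplier
};

enum MoveId {
  MV_SNNI = 0, MV_ESPR = 1, MV_ETBR = 2,
  MV_PSPR1 = 3, MV_PSPR2 = 4, MV_PTBR1 = 5, MV_PTBR2 = 6,
  MV_BRLEN = 7, MV_TREELEN = 8,
  MV_ALPHA = 9, MV_EXCH = 10, MV_KAPPA = 11
};

struct Proposal {
  bool valid = false;
  double logH = 0.0;             // full log Hastings incl. scaler multipliers
  double logH_topo = 0.0;        // topology-selection part only
  std::vector<int> touched;      // edge ids whose length was rescaled
  // diagnostics for tests
  int d1 = 0, d2 = 0;            // extension distances / regraft distance
  bool moved2 = false;           // eTBR: second end moved
  bool other_movable = true;     // eTBR: second end was free to move
  bool first_internal = false;   // first extension edge was interior
  bool fwd_con = false, rev_con = false;
  int a = -1, b = -1, q = -1, r = -1; // branch roles (SPR family)
};

// Each proposer mutates `t` in place on success.
Proposal propose_snni(Tree& t, RNG& rng);
Proposal propose_espr(Tree& t, RNG& rng, const Tuning& tn);
Proposal propose_etbr(Tree& t, RNG& rng, const Tuning& tn);
Proposal propose_pspr(Tree& t, const PatternData* guide, RNG& rng,
                      const Tuning& tn, int variant, bool hastings_on);
Proposal propose_ptbr(Tree& t, const PatternData* guide, RNG& rng,
                      const Tuning& tn, int variant, bool hastings_on);
Proposal propose_tree_move(int move, Tree& t, const PatternData* guide,
                           RNG& rng, const Tuning& tn, bool hastings_on);
Tuning tuning_from_R(Rcpp::List tl);

// Guide weight on the log scale for a candidate parsimony score S.
inline double guide_logw(double S, int variant, const Tuning& tn, double N) {
  if (variant == 1) return -tn.eps1 * S;
  double vhat = S / N + tn.eta;
  double rho = tn.rho_factor * (1.0 - std::exp(-4.0 * vhat / 3.0));
  return tn.eps2 * S * std::log(rho);
}

// ---------------------------------------------------------------------------
// Substitution models / likelihood
// ---------------------------------------------------------------------------
struct Model {
  int id = 0;                    // 0 JC69, 1 K80, 2 GTR
  double kappa = 1.0;
  std::array<double,6> exch {{1,1,1,1,1,1}};   // AC AG AT CG CT GT
  std::array<double,4> pi {{0.25,0.25,0.25,0.25}};
  int ncat = 1;
  double alpha = 1.0;            // gamma shape (used when ncat > 1)
  std::vector<double> rates;     // category rate multipliers, mean 1
  // GTR eigen system of diag(sqrt(pi)) Q diag(1/sqrt(pi))
  std::array<double,16> V {};    // eigenvectors (columns)
  std::array<double,4>  lam {};
  void update();                 // refresh rates and eigen system
};

Model model_from_R(Rcpp::List m);
void transition_matrix(const Model& m, double v, double rate, double P[4][4]);
double log_likelihood(const Tree& t, const PatternData& d, const Model& m);
std::vector<double> discrete_gamma_rates(double alpha, int ncat);

// ---------------------------------------------------------------------------
// Priors
// ---------------------------------------------------------------------------
struct PriorCfg {
  int brlen_kind = 1;            // 0 exponential, 1 gamma-Dirichlet
  double exp_rate = 10.0;
  double aT = 1.0, bT = 0.1, ac = 1.0, cc = 1.0;
  double alpha_rate = 1.0;       // Exponential prior on gamma shape
  double kappa_rate = 0.1;       // Exponential prior on kappa
};

PriorCfg prior_from_R(Rcpp::List p);
double log_prior_brlen(const Tree& t, const PriorCfg& p);

#endif
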