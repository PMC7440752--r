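#include "pgmcmc.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Discrete gamma (equal-probability categories, mean category rates)
// ---------------------------------------------------------------------------
std::vector<double> discrete_gamma_rates(double alpha, int ncat) {
  std::vector<double> r(ncat, 1.0);
  if (ncat == 1) return r;
  double scale = 1.0 / alpha;
  auto pg1 = [&](double x) { return R::pgamma(x, alpha + 1.0, scale, 1, 0); };
  double prev_q = 0.0, prev_p = 0.0;
  for (int k = 0; k < ncat; ++k) {
    double q = (k == ncat - 1) ? R_PosInf
                               : R::qgamma((k + 1.0) / ncat, alpha, scale, 1, 0);
    double p = (k == ncat - 1) ? 1.0 : pg1(q);
    r[k] = ncat * (p - prev_p);
    prev_q = q; prev_p = p;
  }
  (void)prev_q;
  return r;
}

// ---------------------------------------------------------------------------
// Symmetric 4x4 Jacobi eigen decomposition
// ---------------------------------------------------------------------------
static void jacobi4(double A[4][4], double V[4][4], double lam[4]) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) V[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 100; ++sweep) {
    double off = 0;
    for (int p = 0; p < 4; ++p)
      for (int q = p + 1; q < 4; ++q) off += A[p][q] * A[p][q];
    if (off < 1e-26) break;
    for (int p = 0; p < 4; ++p)
      for (int q = p + 1; q < 4; ++q) {
        if (std::fabs(A[p][q]) < 1e-30) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
        double tt = (theta >= 0 ? 1.0 : -1.0) /
                    (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(tt * tt + 1.0), s = tt * c;
        for (int k = 0; k < 4; ++k) {
          double akp = A[k][p], akq = A[k][q];
          A[k][p] = c * akp - s * akq;
          A[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 4; ++k) {
          double apk = A[p][k], aqk = A[q][k];
          A[p][k] = c * apk - s * aqk;
          A[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 4; ++k) {
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
  }
  for (int i = 0; i < 4; ++i) lam[i] = A[i][i];
}

void Model::update() {
  rates = discrete_gamma_rates(alpha, ncat);
  if (id != 2) return;
  // GTR rate matrix, mean rate 1, then symmetrized eigen system
  double Q[4][4] = {{0}};
  int idx = 0;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j) {
      Q[i][j] = exch[idx] * pi[j];
      Q[j][i] = exch[idx] * pi[i];
      ++idx;
    }
  double mu = 0;
  for (int i = 0; i < 4; ++i) {
    double s = 0;
    for (int j = 0; j < 4; ++j) if (j != i) s += Q[i][j];
    Q[i][i] = -s;
    mu += pi[i] * s;
  }
  double B[4][4], Vt[4][4], l[4];
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      B[i][j] = std::sqrt(pi[i]) * (Q[i][j] / mu) / std::sqrt(pi[j]);
  jacobi4(B, Vt, l);
  for (int i = 0; i < 4; ++i) {
    lam[i] = l[i];
    for (int j = 0; j < 4; ++j) V[i * 4 + j] = Vt[i][j];
  }
}

Model model_from_R(List m) {
  Model md;
  std::string id = as<std::string>(m["id"]);
  md.id = (id == "JC69") ? 0 : (id == "K80") ? 1 : 2;
  if (m.containsElementNamed("kappa")) md.kappa = as<double>(m["kappa"]);
  if (m.containsElementNamed("exch")) {
    NumericVector e = m["exch"];
    for (int i = 0; i < 6; ++i) md.exch[i] = e[i];
  }
  if (m.containsElementNamed("pi")) {
    NumericVector p = m["pi"];
    for (int i = 0; i < 4; ++i) md.pi[i] = p[i];
  }
  if (m.containsElementNamed("ncat")) md.ncat = as<int>(m["ncat"]);
  if (m.containsElementNamed("alpha")) md.alpha = as<double>(m["alpha"]);
  md.update();
  return md;
}

void transition_matrix(const Model& m, double v, double rate, double P[4][4]) {
  double t = v * rate;
  if (m.id == 0) {
    double e = std::exp(-4.0 * t / 3.0);
    double ps = 0.25 + 0.75 * e, pd = 0.25 - 0.25 * e;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) P[i][j] = (i == j) ? ps : pd;
  } else if (m.id == 1) {
    double beta = 1.0 / (m.kappa + 2.0);
    double e1 = std::exp(-4.0 * beta * t);
    double e2 = std::exp(-2.0 * beta * (m.kappa + 1.0) * t);
    double ps = 0.25 + 0.25 * e1 + 0.5 * e2;
    double pts = 0.25 + 0.25 * e1 - 0.5 * e2;    // transition
    double ptv = 0.25 - 0.25 * e1;               // each transversion
    // state order A C G T; transitions A<->G, C<->T
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        if (i == j) P[i][j] = ps;
        else if ((i + j) % 2 == 0) P[i][j] = pts; // A(0)G(2), C(1)T(3)
        else P[i][j] = ptv;
      }
  } else {
    double ex[4];
    for (int k = 0; k < 4; ++k) ex[k] = std::exp(m.lam[k] * t);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        double s = 0;
        for (int k = 0; k < 4; ++k) s += m.V[i * 4 + k] * ex[k] * m.V[j * 4 + k];
        double p = s * std::sqrt(m.pi[j] / m.pi[i]);
        P[i][j] = p > 0 ? p : 0.0;
      }
  }
}

// ---------------------------------------------------------------------------
// Pruning likelihood with per-node rescaling
// ---------------------------------------------------------------------------
double log_likelihood(const Tree& t, const PatternData& d, const Model& m) {
  int np = d.npat, K = m.ncat, E = t.nedges();
  // transition matrices per (edge, category)
  std::vector<double> Pm((size_t)E * K * 16);
  for (int e = 0; e < E; ++e) {
    if (!t.act[e]) continue;
    for (int k = 0; k < K; ++k) {
      double P[4][4];
      transition_matrix(m, t.len[e], m.rates[k], P);
      double* dst = &Pm[((size_t)e * K + k) * 16];
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) dst[i * 4 + j] = P[i][j];
    }
  }
  // postorder from the internal node adjacent to tip 0
  int root = t.other(t.adj[0][0], 0);
  std::vector<int> nodes, pedge;
  {
    std::vector<int> sn, se;
    sn.push_back(root); se.push_back(-1);
    while (!sn.empty()) {
      int n = sn.back(); sn.pop_back();
      int pe = se.back(); se.pop_back();
      nodes.push_back(n); pedge.push_back(pe);
      for (int k = 0; k < t.deg[n]; ++k) {
        int e = t.adj[n][k];
        if (e == pe) continue;
        sn.push_back(t.other(e, n)); se.push_back(e);
      }
    }
    std::reverse(nodes.begin(), nodes.end());
    std::reverse(pedge.begin(), pedge.end());
  }
  size_t stride = (size_t)np * K * 4;
  std::vector<double> L((size_t)t.nnodes() * stride);
  std::vector<double> lsc((size_t)np * K, 0.0);
  for (size_t i = 0; i < nodes.size(); ++i) {
    int n = nodes[i];
    double* Ln = &L[(size_t)n * stride];
    if (t.is_tip(n)) {
      // tips hold their state indicators; a tip can still act as the
      // traversal root (2-taxon trees), so children are folded in below
      for (int p = 0; p < np; ++p) {
        uint8_t s = d.st[(size_t)n * np + p];
        for (int k = 0; k < K; ++k)
          for (int x = 0; x < 4; ++x)
            Ln[((size_t)p * K + k) * 4 + x] = (s >> x) & 1 ? 1.0 : 0.0;
      }
    } else {
      for (size_t z = 0; z < stride; ++z) Ln[z] = 1.0;
    }
    for (int kk = 0; kk < t.deg[n]; ++kk) {
      int e = t.adj[n][kk];
      if (e == pedge[i]) continue;
      const double* Lc = &L[(size_t)t.other(e, n) * stride];
      for (int p = 0; p < np; ++p)
        for (int k = 0; k < K; ++k) {
          const double* Pk = &Pm[((size_t)e * K + k) * 16];
          const double* lc = &Lc[((size_t)p * K + k) * 4];
          double* ln = &Ln[((size_t)p * K + k) * 4];
          for (int x = 0; x < 4; ++x) {
            double s = Pk[x * 4 + 0] * lc[0] + Pk[x * 4 + 1] * lc[1]
                     + Pk[x * 4 + 2] * lc[2] + Pk[x * 4 + 3] * lc[3];
            ln[x] *= s;
          }
        }
    }
    // rescale
    for (int p = 0; p < np; ++p)
      for (int k = 0; k < K; ++k) {
        double* ln = &Ln[((size_t)p * K + k) * 4];
        double mx = ln[0];
        for (int x = 1; x < 4; ++x) if (ln[x] > mx) mx = ln[x];
        if (mx > 0 && mx < 1e-80) {
          for (int x = 0; x < 4; ++x) ln[x] /= mx;
          lsc[(size_t)p * K + k] += std::log(mx);
        }
      }
  }
  const double* Lr = &L[(size_t)root * stride];
  double total = 0.0;
  for (int p = 0; p < np; ++p) {
    double best = -INFINITY;
    std::array<double, 8> lk;
    for (int k = 0; k < K; ++k) {
      const double* lr = &Lr[((size_t)p * K + k) * 4];
      double s = 0;
      for (int x = 0; x < 4; ++x) s += m.pi[x] * lr[x];
      double v = (s > 0 ? std::log(s) : -INFINITY) + lsc[(size_t)p * K + k];
      lk[k] = v;
      if (v > best) best = v;
    }
    double acc = 0;
    for (int k = 0; k < K; ++k) acc += std::exp(lk[k] - best);
    total += d.w[p] * (best + std::log(acc) - std::log((double)K));
  }
  return total;
}

// ---------------------------------------------------------------------------
// Priors
// ---------------------------------------------------------------------------
PriorCfg prior_from_R(List p) {
  PriorCfg pc;
  std::string kind = as<std::string>(p["brlen"]);
  pc.brlen_kind = (kind == "exponential") ? 0 : 1;
  if (p.containsElementNamed("exp_rate")) pc.exp_rate = as<double>(p["exp_rate"]);
  if (p.containsElementNamed("gd")) {
    NumericVector g = p["gd"];
    pc.aT = g[0]; pc.bT = g[1]; pc.ac = g[2]; pc.cc = g[3];
  }
  if (p.containsElementNamed("alpha_rate")) pc.alpha_rate = as<double>(p["alpha_rate"]);
  if (p.containsElementNamed("kappa_rate")) pc.kappa_rate = as<double>(p["kappa_rate"]);
  return pc;
}

double log_prior_brlen(const Tree& t, const PriorCfg& p) {
  double T = 0;
  int B = 0, nint = 0;
  for (int e = 0; e < t.nedges(); ++e) {
    if (!t.act[e]) continue;
    if (t.len[e] < 0 || !std::isfinite(t.len[e])) return -INFINITY;
    T += t.len[e];
    ++B;
    if (t.edge_internal(e)) ++nint;
  }
  if (p.brlen_kind == 0) {
    double lp = 0;
    for (int e = 0; e < t.nedges(); ++e)
      if (t.act[e]) lp += std::log(p.exp_rate) - p.exp_rate * t.len[e];
    return lp;
  }
  if (T <= 0) return -INFINITY;
  int next = B - nint;
  double aext = p.ac, aint = p.ac * p.cc;
  // tree length ~ Gamma(aT, rate bT)
  double lp = p.aT * std::log(p.bT) - R::lgammafn(p.aT)
            + (p.aT - 1.0) * std::log(T) - p.bT * T;
  // proportions ~ Dirichlet(aext...,aint...) with the (v)->(T, props) Jacobian
  lp += R::lgammafn(next * aext + nint * aint)
      - next * R::lgammafn(aext) - nint * R::lgammafn(aint);
  for (int e = 0; e < t.nedges(); ++e) {
    if (!t.act[e]) continue;
    double conc = t.edge_internal(e) ? aint : aext;
    if (conc != 1.0) {
      if (t.len[e] <= 0) return -INFINITY;
      lp += (conc - 1.0) * std::log(t.len[e] / T);
    }
  }
  lp -= (B - 1) * std::log(T);
  return lp;
}

// ---------------------------------------------------------------------------
// Parameter proposals (shape/kappa multipliers, exchangeability Dirichlet)
// ---------------------------------------------------------------------------
static double rnorm01(RNG& rng) {
  double u1 = rng.u(), u2 = rng.u();
  if (u1 < 1e-300) u1 = 1e-300;
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

static double rgamma_mt(double shape, RNG& rng) {
  if (shape < 1.0) {
    double u = rng.u();
    if (u < 1e-300) u = 1e-300;
    return rgamma_mt(shape + 1.0, rng) * std::pow(u, 1.0 / shape);
  }
  double d = shape - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
  while (true) {
    double x = rnorm01(rng);
    double v = 1.0 + c * x;
    if (v <= 0) continue;
    v = v * v * v;
    double u = rng.u();
    if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
    if (u < 1e-300) u = 1e-300;
    if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
  }
}

static double ldirichlet(const std::array<double,6>& x, const std::array<double,6>& a) {
  double s = 0, lp = 0;
  for (int i = 0; i < 6; ++i) { s += a[i]; lp -= R::lgammafn(a[i]); }
  lp += R::lgammafn(s);
  for (int i = 0; i < 6; ++i) lp += (a[i] - 1.0) * std::log(x[i]);
  return lp;
}

// ---------------------------------------------------------------------------
// The Metropolis(-coupled) driver
// ---------------------------------------------------------------------------
struct Chain {
  Tree t;
  Model m;
  double logL = 0, logPr = 0;
};

// [[Rcpp::export]]
List cpp_mcmc_run(List cfg) {
  int ntips = as<int>(cfg["ntips"]);
  Tree t0 = tree_from_R(ntips, cfg["edge"], cfg["length"]);
  CharacterVector labR = cfg["labels"];
  std::vector<std::string> labels(ntips);
  for (int i = 0; i < ntips; ++i) labels[i] = as<std::string>(labR[i]);

  bool use_lik = as<bool>(cfg["use_likelihood"]);
  bool hastings_on = cfg.containsElementNamed("hastings_on")
                     ? as<bool>(cfg["hastings_on"]) : true;
  PatternData data, guide;
  bool has_data = false, has_guide = false;
  if (cfg.containsElementNamed("data") && !Rf_isNull(cfg["data"])) {
    data = patterns_from_R(cfg["data"]); has_data = true;
  }
  if (cfg.containsElementNamed("guide") && !Rf_isNull(cfg["guide"])) {
    guide = patterns_from_R(cfg["guide"]); has_guide = true;
  }
  if (use_lik && !has_data) stop("likelihood requested without data");

  Model m0 = model_from_R(cfg["model"]);
  PriorCfg prior = prior_from_R(cfg["prior"]);
  Tuning tn = tuning_from_R(cfg["tuning"]);
  IntegerVector smove = cfg["schedule_moves"];
  NumericVector swt = cfg["schedule_weights"];
  int nmv = smove.size();
  std::vector<double> cumw(nmv);
  double wtot = 0;
  for (int i = 0; i < nmv; ++i) { wtot += swt[i]; cumw[i] = wtot; }

  double generations = as<double>(cfg["generations"]);
  int sample_every = as<int>(cfg["sample_every"]);
  int nchains = as<int>(cfg["nchains"]);
  double heat = as<double>(cfg["heat_lambda"]);
  bool sample_alpha = cfg.containsElementNamed("sample_alpha")
                      ? as<bool>(cfg["sample_alpha"]) : false;
  bool sample_kappa = cfg.containsElementNamed("sample_kappa")
                      ? as<bool>(cfg["sample_kappa"]) : false;
  bool sample_exch = cfg.containsElementNamed("sample_exch")
                     ? as<bool>(cfg["sample_exch"]) : false;
  RNG rng((uint64_t)as<double>(cfg["seed"]));

  auto param_logprior = [&](const Model& m) {
    double lp = 0;
    if (sample_alpha) lp += std::log(prior.alpha_rate) - prior.alpha_rate * m.alpha;
    if (sample_kappa) lp += std::log(prior.kappa_rate) - prior.kappa_rate * m.kappa;
    return lp;   // flat Dirichlet on exchangeabilities contributes a constant
  };

  std::vector<Chain> ch(nchains);
  std::vector<double> beta(nchains);
  for (int i = 0; i < nchains; ++i) {
    ch[i].t = t0;
    ch[i].m = m0;
    ch[i].logL = use_lik ? log_likelihood(t0, data, m0) : 0.0;
    ch[i].logPr = log_prior_brlen(t0, prior) + param_logprior(m0);
    beta[i] = 1.0 / (1.0 + heat * i);
  }

  long G = (long)generations;
  long nsamp_max = G / sample_every + 1;
  std::vector<double> s_gen, s_logL, s_logPr, s_TL;
  std::vector<std::string> s_newick;
  s_gen.reserve(nsamp_max); s_logL.reserve(nsamp_max);
  s_logPr.reserve(nsamp_max); s_TL.reserve(nsamp_max);
  s_newick.reserve(nsamp_max);
  bool do_splits = (ntips <= 31);
  std::vector<int> s_splits;
  if (do_splits) s_splits.reserve(nsamp_max * (ntips - 3));

  std::vector<long> nprop(12, 0), nacc(12, 0);
  long swap_prop = 0, swap_acc = 0;

  auto record = [&](long g) {
    const Chain& c = ch[0];
    s_gen.push_back((double)g);
    s_logL.push_back(c.logL);
    s_logPr.push_back(c.logPr);
    double T = 0;
    for (int e = 0; e < c.t.nedges(); ++e) if (c.t.act[e]) T += c.t.len[e];
    s_TL.push_back(T);
    s_newick.push_back(tree_newick(c.t, labels));
    if (do_splits) {
      std::vector<uint32_t> sp = tree_splits(c.t);
      for (size_t k = 0; k < sp.size(); ++k) s_splits.push_back((int)sp[k]);
    }
  };
  record(0);

  for (long g = 1; g <= G; ++g) {
    for (int ci = 0; ci < nchains; ++ci) {
      Chain& c = ch[ci];
      double u = rng.u() * wtot;
      int mi = 0;
      while (mi < nmv - 1 && u > cumw[mi]) ++mi;
      int mv = smove[mi];
      if (ci == 0) ++nprop[mv];
      double logH = 0, newL = c.logL, newPr = 0;
      bool structural = false;
      Tree tc = c.t;
      Model mc = c.m;
      if (mv <= MV_PTBR2) {
        Proposal P = propose_tree_move(mv, tc, has_guide ? &guide : nullptr,
                                       rng, tn, hastings_on);
        if (!P.valid) stop("tree move %d not applicable", mv);
        logH = P.logH;
        structural = true;
      } else if (mv == MV_BRLEN) {
        int e = rng.ui(tc.nedges());
        double mmul = std::exp(tn.lam_brlen * (rng.u() - 0.5));
        tc.len[e] *= mmul;
        logH = std::log(mmul);
        structural = true;
      } else if (mv == MV_TREELEN) {
        double mmul = std::exp(tn.lam_tl * (rng.u() - 0.5));
        for (int e = 0; e < tc.nedges(); ++e) tc.len[e] *= mmul;
        logH = tc.nedges() * std::log(mmul);
        structural = true;
      } else if (mv == MV_ALPHA) {
        double mmul = std::exp(2.0 * std::log(1.5) * (rng.u() - 0.5));
        mc.alpha *= mmul;
        mc.update();
        logH = std::log(mmul);
      } else if (mv == MV_KAPPA) {
        double mmul = std::exp(2.0 * std::log(1.5) * (rng.u() - 0.5));
        mc.kappa *= mmul;
        mc.update();
        logH = std::log(mmul);
      } else if (mv == MV_EXCH) {
        double a0 = 100.0;
        std::array<double,6> fwd_a, rev_a, nx;
        double s = 0;
        for (int i = 0; i < 6; ++i) fwd_a[i] = a0 * c.m.exch[i] + 1e-6;
        for (int i = 0; i < 6; ++i) { nx[i] = rgamma_mt(fwd_a[i], rng); s += nx[i]; }
        for (int i = 0; i < 6; ++i) nx[i] /= s;
        for (int i = 0; i < 6; ++i) rev_a[i] = a0 * nx[i] + 1e-6;
        logH = ldirichlet(c.m.exch, rev_a) - ldirichlet(nx, fwd_a);
        mc.exch = nx;
        mc.update();
      }
      newPr = log_prior_brlen(tc, prior) + param_logprior(mc);
      if (use_lik && std::isfinite(newPr)) {
        newL = log_likelihood(tc, data, mc);
      } else if (!use_lik) {
        newL = 0.0;
      }
      bool ok = std::isfinite(newPr) && std::isfinite(newL) && std::isfinite(logH);
      if (ok) {
        double lr = beta[ci] * (newL - c.logL) + (newPr - c.logPr) + logH;
        double uu = rng.u();
        if (uu < 1e-300) uu = 1e-300;
        if (std::log(uu) < lr) {
          c.t = tc; c.m = mc; c.logL = newL; c.logPr = newPr;
          if (ci == 0) ++nacc[mv];
        }
      }
      (void)structural;
    }
    if (nchains > 1) {
      ++swap_prop;
      int i = rng.ui(nchains);
      int j = rng.ui(nchains - 1);
      if (j >= i) ++j;
      double lr = (beta[i] - beta[j]) * (ch[j].logL - ch[i].logL);
      double uu = rng.u();
      if (uu < 1e-300) uu = 1e-300;
      if (std::log(uu) < lr) {
        std::swap(ch[i], ch[j]);
        ++swap_acc;
      }
    }
    if (g % sample_every == 0) record(g);
  }

  int ns = (int)s_gen.size();
  IntegerMatrix splits(do_splits ? ns : 0, do_splits ? std::max(ntips - 3, 0) : 0);
  if (do_splits && ntips > 3) {
    for (int i = 0; i < ns; ++i)
      for (int k = 0; k < ntips - 3; ++k)
        splits(i, k) = s_splits[(size_t)i * (ntips - 3) + k];
  }
  CharacterVector nwk(ns);
  for (int i = 0; i < ns; ++i) nwk[i] = s_newick[i];
  IntegerVector np(12), na(12);
  for (int i = 0; i < 12; ++i) { np[i] = (int)nprop[i]; na[i] = (int)nacc[i]; }
  List final_state = List::create(
      _["tree"] = tree_to_R(ch[0].t),
      _["alpha"] = ch[0].m.alpha, _["kappa"] = ch[0].m.kappa,
      _["exch"] = NumericVector(ch[0].m.exch.begin(), ch[0].m.exch.end()));
  return List::create(
      _["gen"] = wrap(s_gen), _["logL"] = wrap(s_logL), _["logPr"] = wrap(s_logPr),
      _["tree_length"] = wrap(s_TL), _["newick"] = nwk, _["splits"] = splits,
      _["proposed"] = np, _["accepted"] = na,
      _["swap_proposed"] = (double)swap_prop, _["swap_accepted"] = (double)swap_acc,
      _["final"] = final_state);
}

// ---------------------------------------------------------------------------
// Thin exports for the R layer
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_loglik(int ntips, IntegerMatrix edge, NumericVector len,
                  List data, List model) {
  Tree t = tree_from_R(ntips, edge, len);
  PatternData d = patterns_from_R(data);
  if (d.ntax != ntips) stop("data/tree taxon count mismatch");
  Model m = model_from_R(model);
  double ll = log_likelihood(t, d, m);
  if (!std::isfinite(ll)) stop("non-finite log likelihood");
  return ll;
}

// [[Rcpp::export]]
NumericMatrix cpp_transition_matrix(List model, double v, double rate) {
  if (v < 0) stop("branch length must be >= 0");
  Model m = model_from_R(model);
  double P[4][4];
  transition_matrix(m, v, rate, P);
  NumericMatrix out(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = P[i][j];
  return out;
}

// [[Rcpp::export]]
double cpp_log_prior_brlen(int ntips, IntegerMatrix edge, NumericVector len,
                           List prior) {
  Tree t = tree_from_R(ntips, edge, len);
  PriorCfg p = prior_from_R(prior);
  return log_prior_brlen(t, p);
}

// [[Rcpp::export]]
NumericVector cpp_gamma_rates(double alpha, int ncat) {
  std::vector<double> r = discrete_gamma_rates(alpha, ncat);
  return NumericVector(r.begin(), r.end());
}
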