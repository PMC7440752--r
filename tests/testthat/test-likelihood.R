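test_that("transition matrices: identity at v = 0, stationarity at large v", {
  for (m in list(subst_model("JC69"), subst_model("K80", kappa = 4),
                 subst_model("GTR", exch = c(1, 2, 1, 1, 3, 1),
                             pi = c(.4, .1, .3, .2)))) {
    P0 <- transition_matrix(m, 0)
    expect_equal(unname(P0), diag(4), tolerance = 1e-12)
    P <- transition_matrix(m, 0.37)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    Pinf <- transition_matrix(m, 500)
    expect_equal(unname(Pinf), matrix(m$pi, 4, 4, byrow = TRUE),
                 tolerance = 1e-8)
  }
  # JC closed form
  v <- 0.2
  P <- transition_matrix(subst_model("JC69"), v)
  expect_equal(P[1, 1], 0.25 + 0.75 * exp(-4 * v / 3), tolerance = 1e-14)
  expect_equal(P[1, 2], 0.25 - 0.25 * exp(-4 * v / 3), tolerance = 1e-14)
  # K80 nests JC at kappa = 1
  expect_equal(transition_matrix(subst_model("K80", kappa = 1), v),
               transition_matrix(subst_model("JC69"), v), tolerance = 1e-12)
  expect_error(transition_matrix(subst_model("JC69"), -0.1), ">= 0")
})

test_that("engine and R transition matrices agree (incl. GTR Jacobi vs eigen)", {
  m <- subst_model("GTR", exch = c(2, 5, 1, 1, 6, 1) / 16, pi = c(.35, .15, .2, .3))
  for (v in c(0.01, 0.3, 2)) {
    expect_equal(unname(transition_matrix(m, v)),
                 pgmcmc:::cpp_transition_matrix(pgmcmc:::.model_list(m), v, 1),
                 tolerance = 1e-8)
  }
  mk <- subst_model("K80", kappa = 3)
  expect_equal(unname(transition_matrix(mk, 0.4)),
               pgmcmc:::cpp_transition_matrix(pgmcmc:::.model_list(mk), 0.4, 1),
               tolerance = 1e-12)
})

test_that("gamma category rates average to one and match the R quantile route", {
  for (alpha in c(0.2, 0.5, 1, 3)) {
    r <- gamma_category_rates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_equal(r, as.numeric(pgmcmc:::cpp_gamma_rates(alpha, 4)),
                 tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
})

test_that("two-sequence likelihood matches the closed form to 1e-9", {
  # a three-taxon star whose third taxon is entirely missing collapses to
  # the two-sequence likelihood at distance vA + vB
  vA <- 0.17; vB <- 0.23
  n0 <- 37; n1 <- 13   # matching / mismatching (one specific state) sites
  aln <- aln_mat(a = paste(rep("A", n0 + n1), collapse = ""),
                 b = paste(c(rep("A", n0), rep("G", n1)), collapse = ""),
                 c = paste(rep("N", n0 + n1), collapse = ""))
  tr <- read_newick(sprintf("(a:%g,b:%g,c:0.1);", vA, vB))
  v <- vA + vB
  p0 <- 0.25 + 0.75 * exp(-4 * v / 3)
  p1 <- 0.25 - 0.25 * exp(-4 * v / 3)
  expect_equal(log_likelihood(tr, aln, subst_model("JC69")),
               n0 * log(0.25 * p0) + n1 * log(0.25 * p1), tolerance = 1e-9)
})

test_that("likelihood is invariant to the traversal root", {
  set.seed(41)
  tr <- rand_tree(7)
  aln <- rand_aln(tr$labels, 40)
  mod <- subst_model("GTR", exch = c(1, 4, 1, 1, 4, 1), pi = c(.3, .2, .2, .3),
                     gamma_categories = 4, alpha = 0.4)
  l0 <- log_likelihood(tr, aln, mod)
  for (rep in 1:5) {
    perm <- sample(nrow(tr$edge))
    tr2 <- utree(tr$edge[perm, ], tr$length[perm], tr$labels)
    expect_equal(log_likelihood(tr2, aln, mod), l0, tolerance = 1e-9)
  }
  # and to Newick rotation
  tr3 <- read_newick(write_newick(as_utree(ape::rotateConstr(
    ape::as.phylo(tr), rev(tr$labels)))))
  expect_equal(log_likelihood(tr3, aln, mod), l0, tolerance = 1e-7)
})

test_that("likelihoods agree with an independent pruning implementation", {
  skip_if_not_installed("phangorn")
  set.seed(43)
  for (rep in 1:3) {
    tr <- rand_tree(sample(5:9, 1))
    aln <- rand_aln(tr$labels, 80)
    pd <- phangorn::phyDat(aln)
    phy <- ape::as.phylo(tr)
    expect_equal(log_likelihood(tr, aln, subst_model("JC69")),
                 phangorn::pml(phy, pd)$logLik, tolerance = 1e-6)
    bf <- c(.28, .22, .26, .24); Q <- c(1, 3, 1, 1, 3, 1)
    expect_equal(
      log_likelihood(tr, aln, subst_model("GTR", exch = Q, pi = bf,
                                          gamma_categories = 4, alpha = 0.6)),
      phangorn::pml(phy, pd, bf = bf, Q = Q, k = 4, shape = 0.6)$logLik,
      tolerance = 1e-6)
  }
})

test_that("one gamma category and a very large shape agree", {
  set.seed(47)
  tr <- rand_tree(6)
  aln <- rand_aln(tr$labels, 50)
  m1 <- subst_model("K80", kappa = 2)
  m2 <- subst_model("K80", kappa = 2, gamma_categories = 4, alpha = 1e6)
  expect_equal(log_likelihood(tr, aln, m1), log_likelihood(tr, aln, m2),
               tolerance = 1e-4)
})
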