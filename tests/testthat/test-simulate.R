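test_that("zero branch lengths give identical sequences", {
  tr <- tree5()
  tr$length[] <- 0
  set.seed(61)
  sim <- simulate_dna(tr, subst_model("JC69"), 100)
  aln <- attr(sim, "alignment")
  expect_true(all(aln == rep(aln[1, ], each = 5)))
  expect_lte(ncol(sim$states), 4)   # only constant patterns remain
})

test_that("pairwise mismatch fractions match the closed forms", {
  set.seed(62)
  v <- 0.5
  tr <- read_newick(sprintf("(a:%g,b:0,c:0);", v))
  sim <- simulate_dna(tr, subst_model("JC69"), 5e4)
  aln <- attr(sim, "alignment")
  p_mm <- 0.75 * (1 - exp(-4 * v / 3))
  se <- sqrt(p_mm * (1 - p_mm) / 5e4)
  expect_lt(abs(mean(aln["a", ] != aln["b", ]) - p_mm), 3 * se)
  # K80: transition and transversion fractions separately
  k <- 4
  sim2 <- simulate_dna(tr, subst_model("K80", kappa = k), 5e4)
  a2 <- attr(sim2, "alignment")
  beta <- 1 / (k + 2)
  e1 <- exp(-4 * beta * v); e2 <- exp(-2 * beta * (k + 1) * v)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 2 * (0.25 - 0.25 * e1)
  x <- a2["a", ]; y <- a2["b", ]
  ts <- mean((x == "A" & y == "G") | (x == "G" & y == "A") |
             (x == "C" & y == "T") | (x == "T" & y == "C"))
  tv <- mean(x != y) - ts
  expect_lt(abs(ts - p_ts), 3 * sqrt(p_ts * (1 - p_ts) / 5e4))
  expect_lt(abs(tv - p_tv), 3 * sqrt(p_tv * (1 - p_tv) / 5e4))
})

test_that("gamma rate variation increases among-site heterogeneity", {
  set.seed(63)
  tr <- read_newick("(a:0.3,b:0.3,c:0.3);")
  sim <- simulate_dna(tr, subst_model("JC69", gamma_categories = 4,
                                      alpha = 0.3), 2000)
  rates <- attr(sim, "rates")
  expect_equal(mean(rates), 1, tolerance = 0.15)
  expect_gt(stats::var(rates), 1)   # Gamma(0.3, 0.3) has variance 1/0.3
})

test_that("the long-branch fixture misleads parsimony but not likelihood", {
  hit <- 0
  for (s in 1:3) {
    set.seed(s)
    fx <- lba_fixture()
    hit <- hit + fx$lba
    expect_identical(names(which.min(fx$scores)),
                     topology_key(fx$parsimony_tree))
  }
  expect_gte(hit, 3)   # defaults designed to mislead reliably at 10k sites
  # likelihood (true-ish lengths) prefers the generating topology instead
  set.seed(4)
  fx <- lba_fixture()
  keys <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  truekey <- topology_key(fx$tree)
  ll <- vapply(attr(keys, "trees"), function(tt) {
    # truth-like lengths: long terminal branches for C and D, short elsewhere
    tt$length <- rep(0.05, 7)
    for (tax in c("C", "D")) {
      tip <- match(tax, tt$labels)
      tt$length[tt$edge[, 1] == tip | tt$edge[, 2] == tip] <- 0.8
    }
    log_likelihood(tt, fx$data, fx$model)
  }, numeric(1))
  expect_identical(as.character(keys[which.max(ll)]), truekey)
  expect_true(fx$lba)
})

test_that("equal branch lengths remove the systematic attraction", {
  joined <- logical(6)
  for (s in 1:6) {
    set.seed(100 + s)
    fx <- lba_fixture(long = 0.05, short = 0.05, nsites = 2000)
    joined[s] <- grepl("(^|[#;])C,D($|;)", topology_key(fx$parsimony_tree))
  }
  expect_false(all(joined))
})

test_that("the simulator and likelihood are consistent at the generating tree", {
  set.seed(65)
  tr <- rand_tree(6, 0.05, 0.3)
  mod <- subst_model("K80", kappa = 4)
  sim <- simulate_dna(tr, mod, 10000)
  truekey <- topology_key(tr)
  # likelihood over the NNI neighbourhood (lengths fixed at truth) peaks at
  # the generating topology
  ll_true <- log_likelihood(tr, sim, mod)
  for (e in interior_branches(tr)) for (sw in 1:2) {
    alt <- apply_rearrangement(tr, list(type = "nni", branch = e, swap = sw))
    expect_lt(log_likelihood(alt, sim, mod), ll_true)
  }
})
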