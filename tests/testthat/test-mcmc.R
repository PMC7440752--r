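test_that("runs are bit-reproducible under a seed", {
  r1 <- mcmc_run(taxa = 5, generations = 2e4, seed = 3)
  r2 <- mcmc_run(taxa = 5, generations = 2e4, seed = 3)
  expect_identical(r1$newick, r2$newick)
  expect_identical(r1$samples, r2$samples)
  r3 <- mcmc_run(taxa = 5, generations = 2e4, seed = 4)
  expect_false(identical(r1$newick, r3$newick))
})

test_that("schedule presets reproduce the standard move mixes", {
  s <- schedule_preset("simulation", "pSPR1")
  expect_equal(s$weight[s$move == "pSPR1"] / s$weight[s$move == "brlen"], 5)
  m <- subst_model("GTR", gamma_categories = 4, alpha = 1)
  r <- schedule_preset("reference", model = m)
  tree_mass <- sum(r$weight[r$move %in% names(pgmcmc:::.move_ids)[1:7]])
  bl_mass <- sum(r$weight[r$move %in% c("brlen", "treelen")])
  sub_mass <- sum(r$weight[r$move %in% c("alpha", "exch", "kappa")])
  tot <- sum(r$weight)
  expect_equal(100 * tree_mass / tot, 46.67, tolerance = 1e-6)
  expect_equal(100 * bl_mass / tot, 50, tolerance = 1e-6)
  expect_equal(100 * sub_mass / tot, 3.33, tolerance = 1e-6)
  w <- r$weight[match(c("sNNI", "eSPR", "eTBR", "pSPR2", "pTBR2"), r$move)]
  expect_equal(w / w[1], c(1, 2, 1, 2, 1))
  t2 <- schedule_preset("test", mix = "pSPR1+pTBR1", model = m)
  expect_equal(100 * sum(t2$weight[t2$move %in% c("pSPR1", "pTBR1")]) /
                 sum(t2$weight), 36, tolerance = 1e-6)
  expect_equal(100 * sum(t2$weight[t2$move %in% c("brlen", "treelen")]) /
                 sum(t2$weight), 60, tolerance = 1e-6)
  expect_error(pgmcmc:::.check_schedule(data.frame(move = "warp", weight = 1)),
               "unknown moves")
})

test_that("mh_step accepts with probability one when nothing changes the posterior", {
  # sNNI under a constant likelihood maps lengths unchanged, so the
  # posterior ratio and Hastings ratio are both 1
  st <- chain_state(tree5())
  set.seed(8)
  for (i in 1:25) {
    out <- mh_step(st, "sNNI")
    expect_true(out$accepted)
    st <- out$state
  }
  expect_equal(st$logPr, log_prior(st$tree, st$prior))
})

test_that("mh_step runs a small likelihood-based chain coherently", {
  set.seed(9)
  tr <- rand_tree(5)
  aln <- rand_aln(tr$labels, 30)
  st <- chain_state(tr, subst_model("JC69"), prior_config(), data = aln)
  acc <- 0
  for (i in 1:60) {
    out <- mh_step(st, sample(c("eSPR", "brlen", "pSPR2"), 1))
    st <- out$state
    acc <- acc + out$accepted
  }
  expect_gt(acc, 0)
  expect_equal(st$logL, log_likelihood(st$tree, aln, st$model), tolerance = 1e-9)
})

test_that("disabling the Hastings correction skews guided sampling (negative control)", {
  set.seed(10)
  fx_aln <- attr(simulate_dna(read_newick(
    "((C:0.8,A:0.05):0.05,(D:0.8,B:0.05):0.05,E:0.05);"),
    subst_model("K80", kappa = 4), 500), "alignment")
  run <- function(h) mcmc_run(taxa = c("A", "B", "C", "D", "E"),
                              generations = 4e5, seed = 11,
                              guide_data = fx_aln, hastings = h)
  tp_off <- topology_posterior(run(FALSE))
  f_off <- rep(0, 15)
  f_off[seq_along(tp_off)] <- as.vector(tp_off)
  chi <- stats::chisq.test(round(f_off * 3000), p = rep(1 / 15, 15))
  expect_lt(chi$p.value, 1e-3)
  tp_on <- topology_posterior(run(TRUE))
  expect_length(tp_on, 15)
  expect_lt(max(abs(tp_on - 1 / 15)), 0.05)
})

test_that("coupled chains: equal temperatures always swap; heated runs stay correct", {
  r <- mcmc_run(taxa = 5, generations = 2e4, seed = 13, nchains = 3,
                heat_lambda = 0)
  expect_equal(unname(r$swaps["accepted"] / r$swaps["proposed"]), 1)
  r2 <- mcmc_run(taxa = 5, generations = 4e5, seed = 14, nchains = 4,
                 heat_lambda = 0.1)
  tp <- topology_posterior(r2)
  expect_length(tp, 15)
  expect_lt(max(abs(tp - 1 / 15)), 0.025)
})

test_that("run output files round-trip and echo the seed", {
  r <- mcmc_run(taxa = 4, generations = 5e3, seed = 21)
  pre <- tempfile()
  write_run(r, pre)
  ts <- read_tree_samples(paste0(pre, ".trees"))
  expect_equal(length(ts$newick), nrow(r$samples))
  expect_identical(ts$newick, as.character(r$newick))
  expect_equal(ts$gen, r$samples$gen)
  lg <- readLines(paste0(pre, ".log"))
  expect_true(any(grepl("seed: 21", lg)))
  tr <- utils::read.delim(paste0(pre, ".trace.tsv"))
  expect_equal(tr$tree_length, r$samples$tree_length, tolerance = 1e-9)
})

test_that("guidance from a subset of sites is wired through", {
  set.seed(22)
  aln <- rand_aln(paste0("t", 1:5), 200)
  r <- mcmc_run(taxa = paste0("t", 1:5), generations = 1e4, seed = 23,
                guide_data = aln, guide_sites = 50)
  expect_s3_class(r, "pgmcmc_run")
  expect_equal(r$config$guide_sites, 50)
  # config validation reports all problems at once
  err <- tryCatch(run_config(list(mode = "bogus", generations = -1,
                                  burnin = 2)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "mode must be")
  expect_match(err, "generations must be")
  expect_match(err, "burnin must be")
})
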