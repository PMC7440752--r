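test_that("guide weights: equal scores give equal weights; schemes differ", {
  tn <- move_tuning()
  expect_equal(unname(guide_weights(c(12, 12, 12), tn, variant = 1)),
               rep(1, 3))
  w1 <- guide_weights(10:16, tn, variant = 1)
  expect_equal(unname(w1[2]), exp(-0.5), tolerance = 1e-12)
  w2 <- guide_weights(10:16, tn, N = 2000, variant = 2)
  expect_false(isTRUE(all.equal(unname(w1), unname(w2))))
  w2b <- guide_weights(10:16, move_tuning(rho_scheme = "threequarter"),
                       N = 2000, variant = 2)
  expect_false(isTRUE(all.equal(unname(w2), unname(w2b))))
  expect_error(guide_weights(10:12, tn, variant = 2), "site count")
  # engine and R implementations agree up to the common shift
  for (variant in 1:2) {
    lr <- guide_weights(10:16, tn, N = 500, variant = variant, log = TRUE)
    lc <- pgmcmc:::cpp_guide_logw(10:16, variant, unclass(tn), 500)
    expect_equal(unname(lr), lc - lc[1], tolerance = 1e-12)
  }
})

test_that("guided selection Hastings ratio: direct arithmetic and antisymmetry", {
  lw <- log(c(1, exp(-1), exp(-2)))
  got <- log_hastings_guided(lw, b = 1, r = 3)
  expect_equal(got, log((1 / (1 + exp(-1))) / (exp(-2) / (exp(-1) + exp(-2)))),
               tolerance = 1e-12)
  expect_equal(log_hastings_guided(c(0, 0, 0, 0), 2, 4), 0)
  expect_error(log_hastings_guided(lw, 2, 2), "contract violation")
  set.seed(3)
  for (rep in 1:50) {
    k <- sample(3:12, 1)
    lw <- stats::rnorm(k, sd = 2)
    br <- sample(k, 2)
    expect_equal(log_hastings_guided(lw, br[1], br[2]) +
                   log_hastings_guided(lw, br[2], br[1]), 0, tolerance = 1e-10)
  }
})

test_that("branch scaler: identity at u = 0.5, 5% bounds, uniform log multiplier", {
  lam <- 2 * log(1.05)
  expect_equal(scale_branch(0.3, lam, u = 0.5)$value, 0.3)
  expect_equal(scale_branch(0.3, lam, u = 0.5)$log_hastings, 0)
  expect_equal(scale_branch(1, lam, u = 1)$value, 1.05, tolerance = 1e-12)
  expect_equal(scale_branch(1, lam, u = 0)$value, 1 / 1.05, tolerance = 1e-12)
  expect_error(scale_branch(0, lam), "undefined")
  set.seed(4)
  m <- vapply(stats::runif(1e5), function(u) scale_branch(1, lam, u)$log_hastings,
              numeric(1))
  ks <- stats::ks.test(m, "punif", -lam / 2, lam / 2)
  expect_gt(ks$p.value, 1e-4)
})

test_that("every move is Metropolized and returns a valid tree", {
  set.seed(5)
  tr <- rand_tree(7)
  k0 <- topology_key(tr)
  for (mv in c("sNNI", "eSPR", "eTBR", "pSPR1", "pSPR2", "pTBR1", "pTBR2")) {
    p <- propose_move(tr, mv, n = 200, seed = 99, keep_trees = 200)
    keys <- vapply(p$trees, topology_key, "")
    expect_false(any(keys == k0), label = paste(mv, "never re-proposes"))
    for (tt in p$trees[1:10]) {
      expect_s3_class(tt, "utree")           # constructor re-validates
      expect_equal(nrow(tt$edge), 11)
      expect_true(all(tt$length > 0))
    }
    expect_true(all(is.finite(p$logH)))
  }
})

test_that("sNNI has Hastings ratio 1 and maps branch lengths unmodified", {
  set.seed(6)
  tr <- rand_tree(8)
  p <- propose_move(tr, "sNNI", n = 50, seed = 12, keep_trees = 50)
  expect_true(all(p$logH == 0))
  for (tt in p$trees) expect_equal(sort(tt$length), sort(tr$length))
})

test_that("eSPR applies the printed constrained-extension ratios", {
  tr <- balanced_utree(16)
  for (pe in c(0.5, 0.8)) {
    p <- propose_move(tr, "eSPR", move_tuning(pe = pe), n = 2000, seed = 21,
                      keep_trees = 0)
    lt <- round(p$logH_topo, 10)
    both_un <- !p$fwd_constrained & !p$rev_constrained
    both_con <- p$fwd_constrained & p$rev_constrained
    back_only <- !p$fwd_constrained & p$rev_constrained
    fwd_only <- p$fwd_constrained & !p$rev_constrained
    expect_true(all(lt[both_un] == 0))
    expect_true(all(lt[both_con] == 0))
    expect_true(all(abs(lt[back_only] - log(1 / (2 * (1 - pe)))) < 1e-9))
    expect_true(all(abs(lt[fwd_only] - log(2 * (1 - pe))) < 1e-9))
    expect_true(any(back_only) && any(fwd_only))
  }
})

test_that("proposed rearrangements are invertible at the branch level", {
  set.seed(7)
  tr <- rand_tree(8)
  for (mv in c("eSPR", "pSPR1", "pSPR2")) {
    for (i in 1:60) {
      p <- propose_move(tr, mv, seed = i)
      br <- p$branches
      tp <- p$tree
      x <- intersect(tp$edge[br["a"], ], tp$edge[br["q"], ])
      ra <- setdiff(tp$edge[br["a"], ], x)
      inv <- apply_rearrangement(tp, list(type = "spr", branch = br[["a"]],
                                          side = ra, regraft = br[["b"]],
                                          pendant = br[["q"]]))
      expect_identical(topology_key(inv), topology_key(tr))
    }
  }
})

test_that("with constant data the guided regraft choice is uniform over B minus b", {
  tr <- tree5()
  aln <- matrix("G", 5, 20, dimnames = list(tr$labels, NULL))
  p <- propose_move(tr, "pSPR2", data = aln, n = 3e4, seed = 31, keep_trees = 0)
  combo <- paste(p$a, p$b)
  top <- names(sort(table(combo), decreasing = TRUE))[1]
  rs <- p$r[combo == top]
  tab <- table(rs)
  expect_gte(length(tab), 4)   # all remainder branches except the bridge
  chi <- stats::chisq.test(tab)
  expect_gt(chi$p.value, 1e-4)
})

test_that("candidate-set sizes respect the stated bounds", {
  tr <- rand_tree(12)
  a <- which(tr$edge[, 1] <= 12 | tr$edge[, 2] <= 12)[1]
  sc <- regraft_scores(tr, branch = a, data = rand_aln(tr$labels, 5))
  expect_lte(length(sc) - 1, 2 * 12 - 5)     # candidates exclude the bridge
  big <- balanced_utree(64)
  # the central branch sees the largest neighbourhood: at most ~2^6 branches
  # per side within delta = 5, i.e. ~4096 candidate pairs
  ab <- interior_branches(big)
  sizes <- vapply(ab, function(e) {
    sc2 <- bisect_scores(big, e, delta = 5, data = rand_aln(big$labels, 2))
    nrow(sc2) * ncol(sc2)
  }, numeric(1))
  expect_lte(max(sizes), 4096)
})

test_that("propose_move is reproducible under a seed", {
  tr <- rand_tree(6)
  p1 <- propose_move(tr, "pTBR2", seed = 77)
  p2 <- propose_move(tr, "pTBR2", seed = 77)
  expect_identical(write_newick(p1$tree), write_newick(p2$tree))
  expect_identical(p1$log_hastings, p2$log_hastings)
})
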