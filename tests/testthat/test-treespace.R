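test_that("newick parsing validates input and suppresses bifurcating roots", {
  t <- read_newick("((A:1,B:1):1,C:1,D:1);")
  expect_equal(t$ntips, 4)
  expect_equal(nrow(t$edge), 5)             # 2n - 3
  rooted <- read_newick("((A:1,B:1):0.5,(C:1,D:1):0.5);")
  expect_identical(topology_key(rooted), topology_key(t))
  # the two root edges merge into one branch of length 0.5 + 0.5
  ab_branch <- which(rooted$edge[, 1] > 4 & rooted$edge[, 2] > 4)
  expect_equal(rooted$length[ab_branch], 1)
  expect_error(suppressWarnings(read_newick("((A:1,B:1")), "malformed")
  expect_error(read_newick("((A:1,A:1):1,C:1,D:1);"), "duplicate")
  expect_error(read_newick("(A:1,B:1);"), "3 tips")
})

test_that("write/parse round trip preserves topology and lengths", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    tr <- rand_tree(n, 0.001, 3)
    tr2 <- read_newick(write_newick(tr))
    expect_identical(topology_key(tr2), topology_key(tr))
    # lengths compared as sorted multisets (branch order may differ)
    expect_equal(sort(tr2$length), sort(tr$length), tolerance = 1e-9)
  }
})

test_that("topology enumeration gives (2n-5)!! distinct stable keys", {
  expect_length(enumerate_topologies(4), 3)
  k5 <- enumerate_topologies(5)
  expect_length(k5, 15)
  expect_length(unique(k5), 15)
  expect_identical(as.character(k5), as.character(enumerate_topologies(5)))
  expect_length(enumerate_topologies(6), 105)
  expect_error(enumerate_topologies(8), "3..7")
  # independent enumeration by phangorn agrees split-for-split
  skip_if_not_installed("phangorn")
  all5 <- phangorn::allTrees(5, tip.label = paste0("t", 1:5))
  k5b <- sort(vapply(all5, function(ph) topology_key(as_utree(ph)), ""))
  expect_identical(sort(as.character(k5)), k5b)
})

test_that("topology keys are invariant to lengths, rotation and node order", {
  a <- read_newick("((A:1,B:2):3,(C:4,D:5):6,E:7);")
  b <- read_newick("(E:1,(D:1,C:1):1,(B:1,A:1):1);")
  c <- read_newick("((A:9,B:9):9,C:9,(D:9,E:9):9);")
  expect_identical(topology_key(a), topology_key(b))
  expect_false(topology_key(a) == topology_key(c))
})

test_that("NNI exchange is an involution that changes the topology", {
  set.seed(7)
  for (rep in 1:20) {
    tr <- rand_tree(sample(5:9, 1))
    ib <- sample(interior_branches(tr), 1)
    x <- tr$edge[ib, 1]; y <- tr$edge[ib, 2]
    ex <- setdiff(which(tr$edge[, 1] == x | tr$edge[, 2] == x), ib)
    ey <- setdiff(which(tr$edge[, 1] == y | tr$edge[, 2] == y), ib)
    ed <- list(type = "nni", branch = ib,
               exchange = c(sample(ex, 1), sample(ey, 1)))
    t1 <- apply_rearrangement(tr, ed)
    expect_false(topology_key(t1) == topology_key(tr))
    t0 <- apply_rearrangement(t1, ed)
    expect_identical(topology_key(t0), topology_key(tr))
    expect_equal(t0$length, tr$length)
  }
})

test_that("SPR regrafting one node away equals an NNI", {
  set.seed(11)
  for (rep in 1:20) {
    tr <- rand_tree(7)
    # prune a tip and regraft at a branch adjacent to the bridge
    a <- sample(which(tr$edge[, 1] <= 7 | tr$edge[, 2] <= 7), 1)
    ctx <- prune_context(tr, a)
    s <- .surg(tr)
    x <- .surg_other(s, a, ctx$side)
    s2 <- .surg_prune(s, a, x, ctx$pendant, ctx$bridge)
    adjacent <- setdiff(unique(c(.surg_adj(s2, s2$eu[ctx$bridge]),
                                 .surg_adj(s2, s2$ev[ctx$bridge]))), ctx$bridge)
    r <- sample(adjacent, 1)
    t1 <- apply_rearrangement(tr, list(type = "spr", branch = a,
                                       side = ctx$side, regraft = r,
                                       pendant = ctx$pendant))
    expect_true(topology_key(t1) %in% nni_neighbourhood(tr))
  }
})

test_that("a random SPR followed by its inverse restores topology and lengths", {
  set.seed(23)
  for (rep in 1:100) {
    tr <- rand_tree(8)
    repeat {
      a <- sample(nrow(tr$edge), 1)
      u <- tr$edge[a, 1]; v <- tr$edge[a, 2]
      side <- if (u <= 8) u else if (v <= 8) v else sample(c(u, v), 1)
      x <- if (tr$edge[a, 1] == side) tr$edge[a, 2] else tr$edge[a, 1]
      if (x > 8) break
    }
    ee <- setdiff(which(tr$edge[, 1] == x | tr$edge[, 2] == x), a)
    q <- sample(ee, 1); b <- setdiff(ee, q)
    s <- .surg_prune(.surg(tr), a, x, q, b)
    cands <- which(s$act & !is.na(vapply(seq_along(s$act), function(e)
      if (s$act[e]) .surg_near(s, b, e) else NA_integer_, integer(1))))
    if (!length(cands)) next
    r <- sample(cands, 1)
    t1 <- apply_rearrangement(tr, list(type = "spr", branch = a, side = side,
                                       regraft = r, pendant = q))
    expect_false(topology_key(t1) == topology_key(tr))
    t0 <- apply_rearrangement(t1, list(type = "spr", branch = a, side = side,
                                       regraft = b, pendant = q))
    expect_identical(topology_key(t0), topology_key(tr))
    expect_equal(t0$length, tr$length)
  }
})

test_that("rearrangements reject the excluded branches and invalid edits", {
  tr <- tree5()
  tipb <- which(tr$edge[, 1] <= 5 | tr$edge[, 2] <= 5)[1]
  ctx <- prune_context(tr, tipb)
  expect_error(apply_rearrangement(tr, list(type = "spr", branch = tipb,
                                            side = ctx$side,
                                            regraft = ctx$bridge,
                                            pendant = ctx$pendant)),
               "contract violation")
  expect_error(apply_rearrangement(tr, list(type = "nni", branch = tipb,
                                            swap = 1)),
               "interior")
  ib <- interior_branches(tr)
  expect_error(apply_rearrangement(tr, list(type = "tbr", branch = ib[1],
                                            reconnect1 = NA, reconnect2 = NA)),
               NA)  # keeping both ends is allowed at the surgery level
})

test_that("TBR reconnection away from the identity pair changes the topology", {
  set.seed(31)
  tr <- rand_tree(8)
  a <- sample(interior_branches(tr), 1)
  sc <- bisect_scores(tr, a, delta = 5,
                      data = rand_aln(tr$labels, 10))
  idp <- attr(sc, "identity_pair")
  c1 <- as.integer(rownames(sc)); c2 <- as.integer(colnames(sc))
  for (i in c1) for (j in c2) {
    if (i == idp[1] && j == idp[2]) next
    t1 <- apply_rearrangement(tr, list(type = "tbr", branch = a,
                                       reconnect1 = i, reconnect2 = j))
    expect_false(topology_key(t1) == topology_key(tr))
    expect_equal(sort(t1$length), sort(tr$length))
  }
})
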