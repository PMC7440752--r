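test_that("fitch_score matches hand and exhaustive-enumeration results", {
  t4 <- read_newick("((t1:1,t2:1):1,t3:1,t4:1);")
  aln0 <- matrix("A", 4, 3, dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(t4, aln0), 0)
  aln1 <- aln_mat(t1 = "A", t2 = "A", t3 = "G", t4 = "G")
  expect_equal(fitch_score(t4, aln1), 1)
  expect_equal(fitch_oracle(t4, aln1), 1)
  t5 <- read_newick("((t1:1,t2:1):1,(t3:1,(t4:1,t5:1):1):1);")
  aln2 <- aln_mat(t1 = "A", t2 = "C", t3 = "G", t4 = "T", t5 = "T")
  expect_equal(fitch_score(t5, aln2), 3)
  expect_equal(fitch_oracle(t5, aln2), 3)
})

test_that("fitch_score equals the exhaustive oracle and phangorn on random data", {
  set.seed(13)
  for (rep in 1:15) {
    n <- sample(4:6, 1)
    tr <- rand_tree(n)
    aln <- rand_aln(tr$labels, 20)
    aln[sample(length(aln), 5)] <- sample(c("N", "R", "-", "Y"), 5, TRUE)
    pm <- pattern_matrix(aln)
    expect_equal(fitch_score(tr, pm), fitch_oracle(tr, pm))
  }
  skip_if_not_installed("phangorn")
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    tr <- rand_tree(n)
    aln <- rand_aln(tr$labels, 40)
    pd <- phangorn::phyDat(aln)
    expect_equal(fitch_score(tr, aln),
                 as.numeric(phangorn::parsimony(ape::as.phylo(tr), pd,
                                                method = "fitch")))
  }
})

test_that("fitch_score is invariant to taxon order and edge-row permutation", {
  set.seed(17)
  tr <- rand_tree(7)
  aln <- rand_aln(tr$labels, 30)
  s0 <- fitch_score(tr, aln)
  expect_equal(fitch_score(tr, aln[sample(7), ]), s0)
  perm <- sample(nrow(tr$edge))
  tr2 <- utree(tr$edge[perm, ], tr$length[perm], tr$labels)
  expect_equal(fitch_score(tr2, aln), s0)
  expect_error(fitch_score(tr, aln[1:5, ]), "not in the data|missing|taxa")
})

test_that("prune_context partitions the taxa and satisfies subadditivity", {
  t5 <- tree5()
  tipb <- which(t5$edge[, 1] <= 5 | t5$edge[, 2] <= 5)[1]
  ctx <- prune_context(t5, branch = tipb)     # prune a tip
  expect_equal(ctx$remainder$ntips, 4)
  expect_equal(nrow(ctx$remainder$edge), 5)   # 2*4 - 3
  expect_identical(sort(c(ctx$taxa_moving, ctx$remainder$labels)),
                   sort(t5$labels))
  expect_length(intersect(ctx$taxa_moving, ctx$remainder$labels), 0)
  set.seed(19)
  for (rep in 1:50) {
    tr <- rand_tree(sample(5:9, 1))
    aln <- rand_aln(tr$labels, 25)
    a <- sample(nrow(tr$edge), 1)
    u <- tr$edge[a, 1]; v <- tr$edge[a, 2]
    side <- if (u <= tr$ntips) u else if (v <= tr$ntips) v else sample(c(u, v), 1)
    ctx <- tryCatch(prune_context(tr, a, side), error = function(e) NULL)
    if (is.null(ctx)) next
    fR <- fitch_score(ctx$remainder,
                      pattern_matrix(aln[ctx$remainder$labels, , drop = FALSE]))
    fA <- if (length(ctx$taxa_moving) >= 3) {
      sub <- ctx$moving_tree
      fitch_score(sub, pattern_matrix(aln[sub$labels, , drop = FALSE]))
    } else 0
    expect_lte(fR + fA, fitch_score(tr, aln))
  }
})

test_that("incremental regraft scores equal brute-force rescoring", {
  set.seed(29)
  for (rep in 1:100) {
    n <- sample(5:10, 1)
    tr <- rand_tree(n)
    aln <- rand_aln(tr$labels, sample(10:50, 1))
    a <- sample(nrow(tr$edge), 1)
    u <- tr$edge[a, 1]; v <- tr$edge[a, 2]
    side <- if (u <= n) u else if (v <= n) v else sample(c(u, v), 1)
    sc <- tryCatch(regraft_scores(tr, branch = a, side = side, data = aln),
                   error = function(e) NULL)
    if (is.null(sc)) next
    b <- attr(sc, "bridge"); q <- attr(sc, "pendant")
    f <- attr(sc, "fitch")
    # identity at the original attachment
    expect_equal(sc[[as.character(b)]],
                 f[["original"]] - f[["moving"]] - f[["remainder"]])
    f0 <- fitch_score(tr, aln)
    for (r in as.integer(names(sc))) {
      if (r == b) next
      t1 <- apply_rearrangement(tr, list(type = "spr", branch = a, side = side,
                                         regraft = r, pendant = q))
      # brute force: rescore the full regrafted tree
      expect_equal(sc[[as.character(r)]] - sc[[as.character(b)]],
                   fitch_score(t1, aln) - f0)
      expect_equal(sc[[as.character(r)]],
                   fitch_score(t1, aln) - f[["moving"]] - f[["remainder"]])
    }
  }
})

test_that("identical sequences give zero regraft scores everywhere", {
  tr <- tree5()
  aln <- matrix("C", 5, 10, dimnames = list(tr$labels, NULL))
  tipb <- which(tr$edge[, 1] <= 5 | tr$edge[, 2] <= 5)[1]
  sc <- regraft_scores(tr, branch = tipb, data = aln)
  expect_true(all(sc == 0))
})

test_that("TBR reconnection scores equal brute-force rescoring", {
  set.seed(37)
  for (rep in 1:30) {
    tr <- rand_tree(7)
    aln <- rand_aln(tr$labels, 30)
    a <- sample(interior_branches(tr), 1)
    sc <- bisect_scores(tr, a, delta = 2, data = aln)
    idp <- attr(sc, "identity_pair")
    f <- attr(sc, "fitch")
    sid <- sc[as.character(idp[1]), as.character(idp[2])]
    expect_equal(sid, fitch_score(tr, aln) - f[["side1"]] - f[["side2"]])
    f0 <- fitch_score(tr, aln)
    for (i in rownames(sc)) for (j in colnames(sc)) {
      if (as.integer(i) == idp[1] && as.integer(j) == idp[2]) next
      t1 <- apply_rearrangement(tr, list(type = "tbr", branch = a,
                                         reconnect1 = as.integer(i),
                                         reconnect2 = as.integer(j)))
      expect_equal(sc[i, j] - sid, fitch_score(t1, aln) - f0)
    }
  }
})

test_that("TBR candidate sets respect the node radius", {
  tr <- balanced_utree(16)
  a <- interior_branches(tr)[7]
  aln <- rand_aln(tr$labels, 5)
  s1 <- bisect_scores(tr, a, delta = 1, data = aln)
  expect_true(all(attr(s1, "dist1") <= 1) && all(attr(s1, "dist2") <= 1))
  expect_lte(nrow(s1), 5)    # bridge + two branches at each interior endpoint
  expect_lte(ncol(s1), 5)
  s5 <- bisect_scores(tr, a, delta = 5, data = aln)
  expect_gte(nrow(s5) * ncol(s5), nrow(s1) * ncol(s1))
  # on a six-taxon balanced tree each side offers at most 2x2 non-trivial
  # pairs at delta = 1 (one bridge endpoint is a tip on each side)
  t6 <- read_newick("((A:1,B:1):1,C:1,((D:1,E:1):1,F:1):1);")
  ib6 <- interior_branches(t6)
  ctr <- ib6[vapply(ib6, function(e)
    length(pgmcmc:::.split_side(t6, e, t6$edge[e, 1])) == 3, TRUE)][1]
  s6 <- bisect_scores(t6, ctr, delta = 1, data = rand_aln(t6$labels, 5))
  expect_lte(nrow(s6), 3)
  expect_lte(ncol(s6), 3)
  expect_error(bisect_scores(tr, which(tr$edge[, 1] <= 16 | tr$edge[, 2] <= 16)[1],
                             delta = 2, data = aln), "interior")
})
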