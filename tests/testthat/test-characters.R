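test_that("pattern compression merges identical columns and keeps N", {
  aln <- matrix("A", 4, 8, dimnames = list(paste0("t", 1:4), NULL))
  pm <- pattern_matrix(aln)
  expect_equal(ncol(pm$states), 1)
  expect_equal(pm$weights, 8)
  expect_equal(pm$nsites, 8)
  expect_equal(sum(pm$weights), pm$nsites)
})

test_that("IUPAC ambiguity codes map to state subsets, gaps to the full set", {
  aln <- aln_mat(a = "ARN", b = "C-Y", c = "G?T", d = "TMW")
  pm <- pattern_matrix(aln)
  ex <- expand_patterns(pm)
  # column 2: R = {A,G}, '-' missing, '?' missing, M = {A,C}
  expect_equal(unname(ex[, 2]), c(1L + 4L, 15L, 15L, 1L + 2L))
  expect_true(all(ex >= 1 & ex <= 15))
})

test_that("input errors carry position information", {
  expect_error(pattern_matrix(aln_mat(a = "ACGT", b = "ACZT")),
               "unknown symbol 'Z' for taxon b at site 3")
  expect_error(pattern_matrix(matrix("A", 2, 2)), "taxon names")
  aln <- matrix("A", 2, 2, dimnames = list(c("x", "x"), NULL))
  expect_error(pattern_matrix(aln), "duplicate taxon")
})

test_that("FASTA and NEXUS readers agree and reject ragged input", {
  aln <- rbind(s1 = c("A", "C", "G", "T", "R"),
               s2 = c("A", "C", "G", "T", "A"),
               s3 = c("A", "-", "G", "T", "A"))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(aln, fa)
  pf <- read_alignment(fa)
  expect_equal(pf$taxa, rownames(aln))
  expect_equal(pf$nsites, 5)
  nx <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "begin data;",
               "dimensions ntax=3 nchar=5;",
               "format datatype=dna gap=- missing=?;",
               "matrix",
               "s1 ACGTR", "s2 ACGTA", "s3 A-GTA", ";", "end;"), nx)
  pn <- read_alignment(nx)
  expect_identical(pn$states, pf$states)
  expect_identical(pn$weights, pf$weights)
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), bad)
  expect_error(read_alignment(bad), "ragged")
})

test_that("compression round-trips the column multiset of simulated data", {
  set.seed(5)
  tr <- rand_tree(6)
  sim <- simulate_dna(tr, subst_model("K80", kappa = 2), 500)
  aln <- attr(sim, "alignment")
  ex <- expand_patterns(sim)
  orig <- apply(matrix(.iupac[aln], nrow = nrow(aln)), 2, paste, collapse = ",")
  back <- apply(ex, 2, paste, collapse = ",")
  expect_equal(sort(orig), sort(back))
})

test_that("parsimony and likelihood are identical on compressed and raw columns", {
  set.seed(9)
  tr <- rand_tree(5)
  aln <- rand_aln(tr$labels, 60)
  pm <- pattern_matrix(aln)
  by_col <- vapply(seq_len(ncol(aln)), function(j)
    fitch_score(tr, pattern_matrix(aln[, j, drop = FALSE])), numeric(1))
  expect_equal(fitch_score(tr, pm), sum(by_col))
  mod <- subst_model("GTR", exch = c(1, 2, 1, 1, 3, 1), pi = c(.3, .2, .3, .2),
                     gamma_categories = 4, alpha = 0.7)
  ll_col <- vapply(seq_len(ncol(aln)), function(j)
    log_likelihood(tr, pattern_matrix(aln[, j, drop = FALSE]), mod), numeric(1))
  expect_equal(log_likelihood(tr, pm, mod), sum(ll_col), tolerance = 1e-9)
})

test_that("empirical frequencies ignore ambiguous cells", {
  aln <- aln_mat(a = "AAAA", b = "CCNN", c = "GG--", d = "TTRR")
  f <- empirical_frequencies(pattern_matrix(aln))
  expect_equal(unname(f), c(4, 2, 2, 2) / 10)
})
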