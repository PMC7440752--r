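# per-site transition probabilities from parent state i at scaled times tvec
.site_probs <- function(model, i, tvec) {
  if (model$id == "JC69") {
    e <- exp(-4 * tvec / 3)
    p <- matrix(0.25 - 0.25 * e, length(tvec), 4)
    p[, i] <- 0.25 + 0.75 * e
    return(p)
  }
  if (model$id == "K80") {
    k <- model$kappa
    beta <- 1 / (k + 2)
    e1 <- exp(-4 * beta * tvec)
    e2 <- exp(-2 * beta * (k + 1) * tvec)
    p <- matrix(0.25 - 0.25 * e1, length(tvec), 4)       # transversions
    ts_partner <- c(3L, 4L, 1L, 2L)[i]                    # A<->G, C<->T
    p[, ts_partner] <- 0.25 + 0.25 * e1 - 0.5 * e2
    p[, i] <- 0.25 + 0.25 * e1 + 0.5 * e2
    return(p)
  }
  # GTR via the symmetrised eigen system: P_i(t)[j] = sum_k A[k,j] e^{lam_k t}
  es <- attr(model, ".eigen")
  if (is.null(es)) {
    P0 <- transition_matrix(model, 0)   # force validation
    pi <- model$pi
    Q <- matrix(0, 4, 4)
    idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (k in seq_len(6)) {
      a <- idx[k, 1]; b <- idx[k, 2]
      Q[a, b] <- model$exch[k] * pi[b]
      Q[b, a] <- model$exch[k] * pi[a]
    }
    diag(Q) <- -rowSums(Q)
    Q <- Q / -sum(pi * diag(Q))
    S <- diag(sqrt(pi)) %*% Q %*% diag(1 / sqrt(pi))
    es <- eigen((S + t(S)) / 2, symmetric = TRUE)
    es$A <- lapply(1:4, function(ii) {
      sweep(es$vectors[ii, ] * t(es$vectors), 2,
            sqrt(model$pi) / sqrt(model$pi[ii]), `*`)
    })
  }
  E <- exp(outer(tvec, es$values))
  p <- E %*% es$A[[i]]
  p[p < 0] <- 0
  p / rowSums(p)
}

#' Simulate sequence evolution along a tree
#'
#' The root state of every site is drawn from the stationary frequencies
#' and states evolve along branches with the model's transition
#' probabilities. When the model carries gamma rate variation
#' (`gamma_categories > 1`), each site gets its own rate drawn from the
#' continuous Gamma(alpha, alpha) distribution. Uses R's RNG.
#'
#' @param tree a [utree] (branch lengths may be 0).
#' @param model a [subst_model].
#' @param nsites number of sites (>= 1).
#' @return A [pattern_matrix]; the uncompressed character alignment is in
#'   attribute `"alignment"` and the per-site rates in attribute `"rates"`.
#' @examples
#' t <- read_newick("((A:0.1,B:0.1):0.1,C:0.1,D:0.1);")
#' sim <- simulate_dna(t, subst_model("K80", kappa = 4), 100)
#' sim
#' @export
simulate_dna <- function(tree, model, nsites) {
  tree <- as_utree(tree)
  stopifnot(nsites >= 1)
  n <- tree$ntips
  rates <- if (model$ncat > 1)
    stats::rgamma(nsites, shape = model$alpha, rate = model$alpha)
  else rep(1, nsites)
  nn <- 2 * n - 2
  states <- matrix(NA_integer_, nn, nsites)
  root <- n + 1L
  states[root, ] <- sample.int(4, nsites, replace = TRUE, prob = model$pi)
  adj <- .tr_adj(tree)
  # preorder traversal from the root
  stack_n <- root; stack_e <- -1L
  while (length(stack_n)) {
    nd <- stack_n[length(stack_n)]; pe <- stack_e[length(stack_e)]
    stack_n <- stack_n[-length(stack_n)]; stack_e <- stack_e[-length(stack_e)]
    for (e in adj[[nd]]) {
      if (e == pe) next
      ch <- if (tree$edge[e, 1] == nd) tree$edge[e, 2] else tree$edge[e, 1]
      v <- tree$length[e]
      for (i in 1:4) {
        idx <- which(states[nd, ] == i)
        if (!length(idx)) next
        if (v == 0) {
          states[ch, idx] <- i
        } else {
          p <- .site_probs(model, i, v * rates[idx])
          u <- stats::runif(length(idx))
          cp <- p %*% upper.tri(diag(4), diag = TRUE)
          states[ch, idx] <- pmin(rowSums(cp < u) + 1L, 4L)
        }
      }
      stack_n <- c(stack_n, ch); stack_e <- c(stack_e, e)
    }
  }
  aln <- matrix(c("A", "C", "G", "T")[states[seq_len(n), ]], nrow = n,
                dimnames = list(tree$labels, NULL))
  pm <- pattern_matrix(aln)
  attr(pm, "alignment") <- aln
  attr(pm, "rates") <- rates
  pm
}

#' Long-branch-attraction verification fixture
#'
#' A five-taxon tree in the classic geometry that misleads parsimony: two
#' long terminal branches (taxa C and D) separated by short interior
#' branches, all other branches short. Sequences are simulated under K80.
#' With the defaults (10,000 sites, kappa = 4, long = 0.8, short = 0.05 —
#' a reconstruction of the usual geometry, configurable) maximum parsimony
#' over all 15 topologies reliably picks the tree that wrongly joins the
#' two long branches, while likelihood prefers the generating topology.
#'
#' @param long,short branch lengths of the long terminal branches and of
#'   all other branches.
#' @param nsites alignment length.
#' @param kappa K80 transition/transversion parameter.
#' @return List with `tree` (the generating [utree]), `parsimony_tree` (the
#'   maximum-parsimony topology over all 15, found by exhaustive Fitch
#'   scoring), `lba` (logical: the parsimony tree joins the two long
#'   branches and differs from the truth), `scores` (the 15 Fitch scores,
#'   named by topology key), `data` (the simulated [pattern_matrix] with
#'   the raw alignment attached) and `model`.
#' @export
lba_fixture <- function(long = 0.8, short = 0.05, nsites = 10000, kappa = 4) {
  nwk <- sprintf("((C:%g,A:%g):%g,(D:%g,B:%g):%g,E:%g);",
                 long, short, short, long, short, short, short)
  tree <- read_newick(nwk)
  model <- subst_model("K80", kappa = kappa)
  data <- simulate_dna(tree, model, nsites)
  keys <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  scores <- vapply(attr(keys, "trees"), fitch_score, numeric(1), data = data)
  names(scores) <- keys
  best <- attr(keys, "trees")[[which.min(scores)]]
  joined <- grepl("(^|[#;])C,D($|;)", topology_key(best))
  list(tree = tree, parsimony_tree = best,
       lba = joined && topology_key(best) != topology_key(tree),
       scores = scores, data = data, model = model)
}

#' Write an alignment to FASTA
#'
#' @param x a character alignment matrix, or a [pattern_matrix] carrying
#'   its uncompressed alignment (as produced by [simulate_dna] and
#'   [read_alignment]).
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, file) {
  if (inherits(x, "pattern_matrix")) {
    x <- attr(x, "alignment")
    if (is.null(x)) stop("pattern matrix does not carry its raw alignment")
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", rownames(x)[i]), con)
    writeLines(paste(x[i, ], collapse = ""), con)
  }
  invisible(file)
}
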