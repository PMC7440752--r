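# Shared fixtures and independent oracles used across the test files.

# internal helpers exercised directly by the reference-surgery tests
.surg <- pgmcmc:::.surg
.surg_prune <- pgmcmc:::.surg_prune
.surg_adj <- pgmcmc:::.surg_adj
.surg_other <- pgmcmc:::.surg_other
.surg_near <- pgmcmc:::.surg_near
.iupac <- pgmcmc:::.iupac

# a fixed 5-taxon tree ((t1,t2),t3,(t4,t5)) with all lengths 0.1
tree5 <- function() read_newick("((t1:0.1,t2:0.1):0.1,t3:0.1,(t4:0.1,t5:0.1):0.1);")

# alignment matrix from per-taxon strings
aln_mat <- function(...) {
  seqs <- c(...)
  do.call(rbind, lapply(stats::setNames(strsplit(seqs, ""), names(seqs)),
                        identity))
}

rand_aln <- function(taxa, nsites) {
  matrix(sample(c("A", "C", "G", "T"), length(taxa) * nsites, replace = TRUE),
         nrow = length(taxa), dimnames = list(taxa, NULL))
}

# Exhaustive parsimony oracle: minimise the number of changes over all
# assignments of states to interior nodes (tips count a change when the
# interior neighbour's state is not in their ambiguity set). Exponential in
# n, usable for n <= 7.
fitch_oracle <- function(tree, pm) {
  pm <- pattern_matrix(pm)
  ord <- match(tree$labels, pm$taxa)
  st <- pm$states[ord, , drop = FALSE]
  n <- tree$ntips
  k <- n - 2
  combos <- as.matrix(expand.grid(rep(list(1:4), k)))
  total <- 0
  for (p in seq_len(ncol(st))) {
    costs <- numeric(nrow(combos))
    for (e in seq_len(nrow(tree$edge))) {
      u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      if (u > n && v > n) {
        costs <- costs + (combos[, u - n] != combos[, v - n])
      } else {
        tip <- min(u, v); int <- max(u, v)
        mask <- st[tip, p]
        costs <- costs + (bitwAnd(mask, bitwShiftL(1L, combos[, int - n] - 1L)) == 0L)
      }
    }
    total <- total + pm$weights[p] * min(costs)
  }
  total
}

# interior branch ids of a utree
interior_branches <- function(tree) {
  which(!(tree$edge[, 1] <= tree$ntips | tree$edge[, 2] <= tree$ntips))
}

# keys of the full NNI neighbourhood of a tree
nni_neighbourhood <- function(tree) {
  keys <- character(0)
  for (e in interior_branches(tree))
    for (sw in 1:2)
      keys <- c(keys, topology_key(
        apply_rearrangement(tree, list(type = "nni", branch = e, swap = sw))))
  unique(keys)
}

# random tree with random lengths (uses R RNG)
rand_tree <- function(n, lmin = 0.02, lmax = 0.5) {
  tr <- random_utree(n)
  tr$length <- stats::runif(2 * n - 3, lmin, lmax)
  tr
}
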