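#' Fitch parsimony score of a tree
#'
#' Minimum weighted number of state changes under equal-cost (Fitch)
#' parsimony, summed over site patterns; ambiguity sets take part as state
#' subsets, so fully missing cells never add steps.
#'
#' @param tree a [utree].
#' @param data a [pattern_matrix] covering at least the tree's taxa.
#' @return The weighted step count (an integer-valued numeric).
#' @examples
#' t <- read_newick("((a:1,b:1):1,c:1,d:1);")
#' aln <- matrix(c("A","A","G","G"), nrow = 4,
#'               dimnames = list(letters[1:4], NULL))
#' fitch_score(t, pattern_matrix(aln))   # one step
#' @export
fitch_score <- function(tree, data) {
  tree <- as_utree(tree)
  cpp_fitch(tree$ntips, tree$edge, .pm_for_tree(pattern_matrix(data), tree))
}

#' Prune a subtree and expose the remainder for candidate scoring
#'
#' Removes the subtree on the `side` end of branch `branch` together with its
#' attachment node and pendant branch; the surviving merged branch ("the
#' branch left behind") keeps the identity and length of the non-pendant
#' branch. The returned context carries everything [regraft_scores] needs.
#'
#' @param tree a [utree].
#' @param branch branch id (edge row) to prune at.
#' @param side node id of the endpoint whose subtree moves; forced to the tip
#'   for a terminal branch (pass `NULL` to accept the forced choice).
#' @param data optional [pattern_matrix] stored for scoring.
#' @param pendant which of the two other branches at the attachment node
#'   travels with the subtree (default: the lower id).
#' @return An object of class `prune_context`.
#' @export
prune_context <- function(tree, branch, side = NULL, data = NULL, pendant = NULL) {
  tree <- as_utree(tree)
  if (tree$ntips < 4) stop("SPR needs at least 4 tips")
  u <- tree$edge[branch, 1]; v <- tree$edge[branch, 2]
  if (.is_tip(tree, u) || .is_tip(tree, v)) {
    forced <- if (.is_tip(tree, u)) u else v
    if (!is.null(side) && side != forced)
      stop("for a terminal branch the moving subtree is the tip node")
    side <- forced
  } else if (is.null(side)) {
    stop("side must be given for an interior branch")
  }
  if (!(side == u || side == v)) stop("side must be an endpoint of the branch")
  s <- .surg(tree)
  x <- .surg_other(s, branch, side)
  ee <- setdiff(.surg_adj(s, x), branch)
  q <- if (is.null(pendant)) min(ee) else pendant
  if (!q %in% ee) stop("pendant must be incident to the attachment node")
  b <- setdiff(ee, q)
  f1 <- .surg_other(s, ee[1], x); f2 <- .surg_other(s, ee[2], x)
  if (.is_tip(tree, f1) && .is_tip(tree, f2))
    stop("no valid regraft candidates: remainder would keep only two tips")
  s <- .surg_prune(s, branch, x, q, b)

  # moving subtree and remainder as stand-alone trees (node ids re-mapped)
  sub <- function(ids) {
    keep_nodes <- sort(unique(c(s$eu[ids], s$ev[ids])))
    tips <- keep_nodes[keep_nodes <= tree$ntips]
    ints <- keep_nodes[keep_nodes > tree$ntips]
    remap <- stats::setNames(seq_along(keep_nodes),
                             c(tips, ints))[as.character(c(s$eu[ids], s$ev[ids]))]
    m <- matrix(remap, ncol = 2)
    list(edge = m, length = s$len[ids], labels = tree$labels[tips], ids = ids)
  }
  # remainder = active component containing the bridge
  act_ids <- which(s$act)
  near_all <- vapply(act_ids, function(e) .surg_near(s, b, e), integer(1))
  comp <- act_ids[!is.na(near_all) | act_ids == b]
  rem <- sub(comp)
  moving_ids <- setdiff(act_ids, comp)
  moving <- if (length(moving_ids)) sub(moving_ids) else NULL
  # the moving subtree rooted at the attachment has a degree-2 root; suppress
  # it so the subtree can stand alone as an unrooted tree (>= 3 tips only)
  moving_tree <- NULL
  if (!is.null(moving) && length(moving$labels) >= 3) {
    edge <- moving$edge; len <- moving$length
    deg <- tabulate(c(edge), nbins = max(edge))
    nd <- which(deg == 2)[1]
    ee <- which(edge[, 1] == nd | edge[, 2] == nd)
    joined <- c(setdiff(edge[ee[1], ], nd), setdiff(edge[ee[2], ], nd))
    newlen <- sum(len[ee])
    edge <- rbind(edge[-ee, , drop = FALSE], joined)
    len <- c(len[-ee], newlen)
    edge[edge > nd] <- edge[edge > nd] - 1L
    moving_tree <- utree(edge, len, moving$labels)
  }
  structure(list(tree = tree, branch = branch, side = side,
                 pendant = q, bridge = b,
                 remainder = if (length(rem$labels) >= 3)
                   utree(rem$edge, rem$length, rem$labels) else rem,
                 remainder_ids = rem$ids,
                 moving = moving, moving_tree = moving_tree,
                 taxa_moving = setdiff(tree$labels, rem$labels),
                 data = if (!is.null(data)) pattern_matrix(data) else NULL),
            class = "prune_context")
}

#' @export
print.prune_context <- function(x, ...) {
  cat("prune context: branch", x$branch, "side", x$side,
      "| pendant", x$pendant, "bridge", x$bridge, "\n")
  invisible(x)
}

#' Parsimony scores of all SPR regraft candidates
#'
#' For every branch *i* of the pruned remainder, the score
#' \eqn{S_i = \mathrm{fitch}(\text{tree with the subtree regrafted at } i)
#' - \mathrm{fitch}(A) - \mathrm{fitch}(\text{remainder})}, computed
#' incrementally from direction-aware Fitch state sets in time proportional
#' to the number of patterns per candidate, and exactly equal to brute-force
#' rescoring. The score at the original attachment (`bridge`) is included.
#'
#' @param ctx a [prune_context] built with `data`, or a [utree] (then
#'   `branch`, `side`, `data`, `pendant` are used as in [prune_context]).
#' @param branch,side,data,pendant see [prune_context].
#' @return Named numeric vector of scores (names are remainder branch ids)
#'   with attributes `bridge` and `pendant`.
#' @export
regraft_scores <- function(ctx, branch = NULL, side = NULL, data = NULL,
                           pendant = NULL) {
  if (inherits(ctx, "prune_context")) {
    tree <- ctx$tree; branch <- ctx$branch; side <- ctx$side
    pendant <- ctx$pendant
    if (is.null(data)) data <- ctx$data
  } else {
    tree <- as_utree(ctx)
    if (is.null(side)) {
      u <- tree$edge[branch, 1]; v <- tree$edge[branch, 2]
      if (.is_tip(tree, u)) side <- u else if (.is_tip(tree, v)) side <- v
      else stop("side must be given for an interior branch")
    }
  }
  if (is.null(data)) stop("pattern data required for scoring")
  pm <- .pm_for_tree(pattern_matrix(data), tree)
  res <- cpp_regraft_scores(tree$ntips, tree$edge, pm, branch, side,
                            if (is.null(pendant)) 0L else as.integer(pendant))
  out <- stats::setNames(res$scores, res$candidates)
  attr(out, "bridge") <- res$bridge
  attr(out, "pendant") <- res$pendant
  attr(out, "fitch") <- c(original = res$fitch_original,
                          moving = res$fitch_moving,
                          remainder = res$fitch_remainder)
  out
}

#' Parsimony scores of TBR reconnection pairs within a node radius
#'
#' Bisects the tree at interior branch `branch` and scores every
#' reconnection pair `(i, j)` with both branches at most `delta` nodes from
#' the bisection point: \eqn{S_{ij}} is the score of the reconnected tree
#' minus the scores of the two halves. The pair reconstructing the current
#' topology (the two bridge branches, at distance 0) is flagged.
#'
#' @param tree a [utree].
#' @param branch interior branch id.
#' @param delta node radius (>= 1).
#' @param data a [pattern_matrix].
#' @return Numeric matrix of scores (rows: side-1 candidates, columns:
#'   side-2 candidates) with candidate ids/distances and the identity pair
#'   in attributes.
#' @export
bisect_scores <- function(tree, branch, delta, data) {
  tree <- as_utree(tree)
  pm <- .pm_for_tree(pattern_matrix(data), tree)
  res <- cpp_bisect_scores(tree$ntips, tree$edge, pm, branch, as.integer(delta))
  out <- res$scores
  dimnames(out) <- list(res$candidates1, res$candidates2)
  attr(out, "dist1") <- stats::setNames(res$dist1, res$candidates1)
  attr(out, "dist2") <- stats::setNames(res$dist2, res$candidates2)
  attr(out, "identity_pair") <- c(res$bridge1, res$bridge2)
  attr(out, "fitch") <- c(side1 = res$fitch_side1, side2 = res$fitch_side2)
  out
}
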