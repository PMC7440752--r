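#' Unrooted binary trees with stable branch identifiers
#'
#' `utree` is the tree class used throughout the package: an unrooted binary
#' topology over `n >= 3` tips with one branch length per branch. Branches are
#' identified by their row in the edge matrix and these identifiers are stable
#' across rearrangements, which is what allows the SPR/TBR moves to map branch
#' lengths from the old to the new tree (the picked branch, the pendant branch
#' moved with it, and the branch left behind all keep their identity).
#'
#' Nodes are numbered `1..n` for tips (matching `labels`) and `n+1..2n-2` for
#' interior nodes; every interior node has degree 3.
#'
#' @param edge integer matrix with `2n-3` rows and two columns of node indices.
#' @param length numeric vector of branch lengths (>= 0), one per edge row.
#' @param labels character vector of `n` unique tip labels.
#' @return An object of class `utree`.
#' @examples
#' t <- read_newick("((A:1,B:1):1,C:1,D:1);")
#' t
#' @export
utree <- function(edge, length, labels) {
  edge <- as.matrix(edge)
  storage.mode(edge) <- "integer"
  n <- length(labels)
  if (n < 3) stop("an unrooted tree needs at least 3 tips")
  if (anyDuplicated(labels)) {
    stop("duplicate tip labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (nrow(edge) != 2 * n - 3)
    stop("expected ", 2 * n - 3, " branches for ", n, " tips, got ", nrow(edge))
  if (length(length) != nrow(edge)) stop("one branch length per branch required")
  if (any(!is.finite(length)) || any(length < 0))
    stop("branch lengths must be finite and >= 0")
  deg <- tabulate(c(edge), nbins = 2 * n - 2)
  if (any(deg[seq_len(n)] != 1L) || (n > 3 && any(deg[(n + 1):(2 * n - 2)] != 3L)) ||
      (n == 3 && deg[n + 1] != 3L))
    stop("not a binary unrooted tree (wrong node degrees)")
  structure(list(ntips = n, edge = edge, length = as.numeric(length),
                 labels = as.character(labels)),
            class = "utree")
}

#' @export
print.utree <- function(x, ...) {
  cat("unrooted binary tree:", x$ntips, "tips,", nrow(x$edge), "branches\n")
  cat("tips:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (x$ntips > 8) "..." else "", "\n")
  cat(write_newick(x), "\n")
  invisible(x)
}

#' Number of branches of an unrooted tree
#'
#' @param tree a [utree].
#' @return `2n - 3` for `n` tips.
#' @export
n_branches <- function(tree) nrow(tree$edge)

.is_tip <- function(tree, node) node <= tree$ntips

.edge_internal <- function(tree) {
  !(tree$edge[, 1] <= tree$ntips | tree$edge[, 2] <= tree$ntips)
}

#' Parse a Newick string or file into an unrooted tree
#'
#' Rooted (bifurcating-root) inputs are unrooted by suppressing the degree-2
#' root and summing its two incident branch lengths. Missing branch lengths
#' default to 0.1.
#'
#' @param text a Newick string; alternatively use `file`.
#' @param file path to a file whose first tree is read.
#' @return A [utree].
#' @examples
#' read_newick("((A:1,B:1):0.5,(C:1,D:1):0.5);")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stop("supply `text` or `file`")
  ph <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file = file),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE))
  if (is.null(ph)) stop("malformed Newick: no tree could be parsed")
  if (inherits(ph, "multiPhylo")) ph <- ph[[1]]
  as_utree(ph)
}

#' Convert an ape `phylo` object to a `utree`
#'
#' @param phy a `phylo`; a rooted tree is unrooted first (root edge lengths
#'   are summed by `ape::unroot`).
#' @return A [utree].
#' @export
as_utree <- function(phy) {
  if (inherits(phy, "utree")) return(phy)
  if (!inherits(phy, "phylo")) stop("expected a `phylo` or `utree` object")
  n <- length(phy$tip.label)
  if (n < 3) stop("an unrooted tree needs at least 3 tips (got ", n, ")")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.1, nrow(phy$edge))
  phy <- ape::unroot(phy)
  if (phy$Nnode != n - 2)
    stop("tree is not binary (", phy$Nnode, " interior nodes for ", n, " tips)")
  utree(phy$edge, phy$edge.length, phy$tip.label)
}

#' @importFrom ape as.phylo
#' @export
as.phylo.utree <- function(x, ...) {
  ape::read.tree(text = write_newick(x))
}

#' Write a tree as a Newick string
#'
#' Branch lengths are written with 10 significant digits so that
#' `read_newick(write_newick(t))` preserves lengths as well as topology.
#'
#' @param tree a [utree].
#' @param file optional path; when given the string is written there.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- as.character(cpp_newick(tree$ntips, tree$edge, tree$length, tree$labels))
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# tips on the `node`-side of branch e (labels), by traversal avoiding e
.split_side <- function(tree, e, node) {
  adj <- .tr_adj(tree)
  seen <- integer(0)
  stack <- node
  block <- e
  visited <- rep(FALSE, 2 * tree$ntips - 2)
  visited[node] <- TRUE
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nd <= tree$ntips) seen <- c(seen, nd)
    for (ee in adj[[nd]]) {
      if (ee == block) next
      m <- if (tree$edge[ee, 1] == nd) tree$edge[ee, 2] else tree$edge[ee, 1]
      if (!visited[m]) {
        visited[m] <- TRUE
        stack <- c(stack, m)
      }
    }
  }
  tree$labels[sort(seen)]
}

.tr_adj <- function(tree) {
  nn <- 2 * tree$ntips - 2
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    adj[[u]] <- c(adj[[u]], e)
    adj[[v]] <- c(adj[[v]], e)
  }
  adj
}

#' Canonical topology identifier
#'
#' Encodes the set of nontrivial splits (taxon bipartitions) of the tree,
#' each split oriented to the side that does not contain the
#' lexicographically first taxon, sorted into a single string. Two trees get
#' equal keys if and only if they induce identical split sets; the key is
#' invariant to branch lengths, node numbering and Newick rotation.
#'
#' @param tree a [utree] (or anything [as_utree] accepts).
#' @return A character scalar.
#' @export
topology_key <- function(tree) {
  tree <- as_utree(tree)
  first <- sort(tree$labels)[1]
  internal <- which(.edge_internal(tree))
  splits <- vapply(internal, function(e) {
    side <- .split_side(tree, e, tree$edge[e, 1])
    if (first %in% side) side <- setdiff(sort(tree$labels), side)
    paste(sort(side), collapse = ",")
  }, character(1))
  paste0(paste(sort(tree$labels), collapse = ","), "#",
         paste(sort(splits), collapse = ";"))
}

#' Enumerate all unrooted binary topologies for small taxon sets
#'
#' Generates every distinct unrooted binary topology by stepwise tip
#' addition; there are \eqn{(2n-5)!!} of them (e.g. 15 for five taxa, so a
#' uniform topology prior puts probability 1/15 on each).
#'
#' @param labels tip labels, or a single integer `n` (3..7) giving tips
#'   `t1..tn`.
#' @return A character vector of topology keys with the corresponding
#'   [utree] objects in attribute `"trees"`.
#' @export
enumerate_topologies <- function(labels) {
  if (is.numeric(labels) && length(labels) == 1)
    labels <- paste0("t", seq_len(labels))
  n <- length(labels)
  if (n < 3 || n > 7)
    stop("topology enumeration is limited to 3..7 taxa ((2n-5)!! explodes)")
  trees <- list(data.frame(u = c("I1", "I1", "I1"), v = labels[1:3],
                           stringsAsFactors = FALSE))
  if (n >= 4) for (k in 4:n) {
    nxt <- vector("list", length(trees) * (2 * k - 5))
    i <- 0L
    newint <- paste0("I", k - 2)
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        t2 <- tr
        vold <- t2$v[e]
        t2$v[e] <- newint
        t2 <- rbind(t2,
                    data.frame(u = newint, v = vold, stringsAsFactors = FALSE),
                    data.frame(u = newint, v = labels[k], stringsAsFactors = FALSE))
        i <- i + 1L
        nxt[[i]] <- t2
      }
    }
    trees <- nxt
  }
  uts <- lapply(trees, function(tr) {
    nodes <- c(labels, paste0("I", seq_len(n - 2)))
    idx <- stats::setNames(seq_along(nodes), nodes)
    utree(cbind(idx[tr$u], idx[tr$v]), rep(0.1, nrow(tr)), labels)
  })
  keys <- vapply(uts, topology_key, character(1))
  structure(keys, trees = uts)
}

#' A random unrooted binary topology
#'
#' Built by stepwise random addition using R's RNG (so it is reproducible
#' under [set.seed]); all branch lengths are set to `brlen`.
#'
#' @param labels tip labels or a single integer `n`.
#' @param brlen branch length assigned to every branch.
#' @return A [utree].
#' @export
random_utree <- function(labels, brlen = 0.1) {
  if (is.numeric(labels) && length(labels) == 1)
    labels <- paste0("t", seq_len(labels))
  n <- length(labels)
  tr <- data.frame(u = c("I1", "I1", "I1"), v = labels[1:3],
                   stringsAsFactors = FALSE)
  if (n >= 4) for (k in 4:n) {
    e <- sample.int(nrow(tr), 1)
    newint <- paste0("I", k - 2)
    vold <- tr$v[e]
    tr$v[e] <- newint
    tr <- rbind(tr, data.frame(u = newint, v = vold, stringsAsFactors = FALSE),
                data.frame(u = newint, v = labels[k], stringsAsFactors = FALSE))
  }
  nodes <- c(labels, paste0("I", seq_len(n - 2)))
  idx <- stats::setNames(seq_along(nodes), nodes)
  utree(cbind(idx[tr$u], idx[tr$v]), rep(brlen, nrow(tr)), labels)
}

#' A balanced unrooted tree on `2^k` tips
#'
#' Two complete binary subtrees of depth `k-1` joined by a central branch;
#' used in the proposal-mechanism experiments.
#'
#' @param n number of tips, a power of two (>= 4).
#' @param brlen branch length for every branch.
#' @return A [utree].
#' @export
balanced_utree <- function(n, brlen = 0.1) {
  if (n < 4 || bitwAnd(n, n - 1L) != 0)
    stop("n must be a power of two, >= 4")
  build <- function(tips) {
    if (length(tips) == 1) return(tips)
    h <- length(tips) / 2
    paste0("(", build(tips[seq_len(h)]), ":", brlen, ",",
           build(tips[h + seq_len(h)]), ":", brlen, ")")
  }
  half <- n / 2
  labs <- paste0("t", seq_len(n))
  nwk <- paste0("(", build(labs[seq_len(half)]), ":", brlen, ",",
                build(labs[half + seq_len(half)]), ":", brlen, ");")
  read_newick(nwk)
}

# ---------------------------------------------------------------------------
# Reference tree surgery (R implementation; the C++ engine mirrors this).
# Internal state: eu/ev/len indexed by stable branch id plus an active mask.
# ---------------------------------------------------------------------------
.surg <- function(tree) {
  list(nt = tree$ntips, eu = tree$edge[, 1], ev = tree$edge[, 2],
       len = tree$length, act = rep(TRUE, nrow(tree$edge)),
       labels = tree$labels)
}

.surg_tree <- function(s) {
  utree(cbind(s$eu[s$act], s$ev[s$act]), s$len[s$act], s$labels)
}

.surg_adj <- function(s, node) {
  which(s$act & (s$eu == node | s$ev == node))
}

.surg_other <- function(s, e, n) if (s$eu[e] == n) s$ev[e] else s$eu[e]

# prune attachment node x (branch a toward the moving subtree, pendant q);
# the bridge b spans x's two former neighbours and keeps its own length
.surg_prune <- function(s, a, x, q, b) {
  fq <- .surg_other(s, q, x)
  fb <- .surg_other(s, b, x)
  s$act[c(a, q)] <- FALSE
  s$eu[b] <- fq; s$ev[b] <- fb
  s
}

# insert x into branch r; the segment facing `near` takes identity q
.surg_regraft <- function(s, x, a, q, r, near) {
  farn <- if (s$eu[r] == near) s$ev[r] else s$eu[r]
  s$eu[q] <- x; s$ev[q] <- near; s$act[q] <- TRUE
  s$eu[r] <- x; s$ev[r] <- farn
  s$act[a] <- TRUE
  s
}

# endpoint of branch e facing branch b (BFS through the tree), within the
# active component containing b
.surg_near <- function(s, b, e) {
  nd <- rep(NA_integer_, 2 * s$nt - 2)
  nd[c(s$eu[b], s$ev[b])] <- 0L
  qn <- c(s$eu[b], s$ev[b])
  near <- rep(NA_integer_, length(s$eu))
  while (length(qn)) {
    n <- qn[1]; qn <- qn[-1]
    for (ee in .surg_adj(s, n)) {
      if (ee == b || !is.na(near[ee])) next
      near[ee] <- n
      m <- .surg_other(s, ee, n)
      if (is.na(nd[m])) { nd[m] <- nd[n] + 1L; qn <- c(qn, m) }
    }
  }
  near[e]
}

#' Apply a described NNI, SPR or TBR rearrangement
#'
#' Deterministic application of a single tree edit; this is the reference
#' implementation of the rearrangement semantics used by the samplers.
#' Branch lengths are mapped by branch identity: the picked branch, the
#' pendant branch moved with it and the branch left behind keep their
#' lengths, and the regrafted-into branch keeps its length on the far
#' segment.
#'
#' @param tree a [utree].
#' @param edit a list describing the edit:
#'   * `list(type = "nni", branch = a, swap = 1 or 2)` exchanges the first
#'     subtree on one side of interior branch `a` with one of the two
#'     subtrees on the other side; `exchange = c(i, j)` names the two
#'     swapped branches explicitly (one on each side), which makes the edit
#'     an involution;
#'   * `list(type = "spr", branch = a, side = node, regraft = r, pendant = q)`
#'     prunes the subtree rooted at node `side` of branch `a` (together with
#'     pendant branch `q`, one of the two other branches at the attachment
#'     node; defaults to the lower id) and regrafts before branch `r`;
#'   * `list(type = "tbr", branch = a, reconnect1 = r1, reconnect2 = r2,
#'     pendant1 =, pendant2 =)` bisects at interior branch `a` and reconnects
#'     each half at the given branch (`r = NA` keeps that end in place).
#' @return The rearranged [utree].
#' @export
apply_rearrangement <- function(tree, edit) {
  s <- .surg(tree)
  type <- match.arg(edit$type, c("nni", "spr", "tbr"))
  if (type == "nni") {
    a <- edit$branch
    if (.is_tip(tree, s$eu[a]) || .is_tip(tree, s$ev[a]))
      stop("NNI requires an interior branch")
    x <- s$eu[a]; y <- s$ev[a]
    ex <- setdiff(.surg_adj(s, x), a)
    ey <- setdiff(.surg_adj(s, y), a)
    if (!is.null(edit$exchange)) {
      eA <- edit$exchange[1]; eC <- edit$exchange[2]
      if (eA %in% ey && eC %in% ex) { tmp <- eA; eA <- eC; eC <- tmp }
      if (!(eA %in% ex && eC %in% ey))
        stop("exchange must name one branch on each side of the NNI branch")
    } else {
      eA <- ex[1]
      eC <- ey[edit$swap]
    }
    rA <- .surg_other(s, eA, x); rC <- .surg_other(s, eC, y)
    s$eu[eA] <- y; s$ev[eA] <- rA
    s$eu[eC] <- x; s$ev[eC] <- rC
    return(.surg_tree(s))
  }
  if (type == "spr") {
    a <- edit$branch; ra <- edit$side; r <- edit$regraft
    if (!(s$eu[a] == ra || s$ev[a] == ra)) stop("side must be an endpoint of branch")
    x <- .surg_other(s, a, ra)
    if (.is_tip(tree, x)) stop("the moving side must leave an interior attachment node")
    ee <- setdiff(.surg_adj(s, x), a)
    q <- if (is.null(edit$pendant)) min(ee) else edit$pendant
    if (!q %in% ee) stop("pendant must be incident to the attachment node")
    b <- setdiff(ee, q)
    if (r == b || r == q || r == a)
      stop("contract violation: cannot regraft at the pruning-point branches")
    s <- .surg_prune(s, a, x, q, b)
    if (!s$act[r]) stop("regraft branch is not in the pruned remainder")
    near <- .surg_near(s, b, r)
    if (is.na(near)) stop("regraft branch is not in the pruned remainder")
    s <- .surg_regraft(s, x, a, q, r, near)
    return(.surg_tree(s))
  }
  # tbr
  a <- edit$branch
  if (.is_tip(tree, s$eu[a]) || .is_tip(tree, s$ev[a]))
    stop("TBR requires an interior branch")
  xx <- c(s$eu[a], s$ev[a])
  rr <- c(edit$reconnect1, edit$reconnect2)
  s$act[a] <- FALSE
  qq <- bb <- origfar <- integer(2)
  moved <- !is.na(rr)
  for (i in 1:2) {
    if (!moved[i]) next
    ee <- .surg_adj(s, xx[i])
    q <- if (i == 1 && !is.null(edit$pendant1)) edit$pendant1
         else if (i == 2 && !is.null(edit$pendant2)) edit$pendant2
         else min(ee)
    if (!q %in% ee) stop("pendant must be incident to the bisection node")
    b <- setdiff(ee, q)
    origfar[i] <- .surg_other(s, q, xx[i])
    fb <- .surg_other(s, b, xx[i])
    s$act[q] <- FALSE
    s$eu[b] <- origfar[i]; s$ev[b] <- fb
    qq[i] <- q; bb[i] <- b
  }
  if (all(moved) && rr[1] == bb[1] && rr[2] == bb[2])
    stop("contract violation: identity reconnection pair")
  for (i in 1:2) {
    if (!moved[i]) next
    if (!s$act[rr[i]]) stop("reconnection branch is not in this half")
    near <- if (rr[i] == bb[i]) origfar[i] else .surg_near(s, bb[i], rr[i])
    if (is.na(near)) stop("reconnection branch is not in this half")
    s <- .surg_regraft(s, xx[i], a, qq[i], rr[i], near)
    s$act[a] <- FALSE        # keep a out until both ends are reattached
  }
  s$act[a] <- TRUE
  .surg_tree(s)
}
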