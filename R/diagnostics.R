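# canonical split string from a tip bitmask (bit i-1 <-> labels[i]);
# the stored side is re-oriented to exclude the lexicographically first taxon
.mask_to_split <- function(mask, labels) {
  side <- labels[bitwAnd(mask, bitwShiftL(1L, seq_along(labels) - 1L)) != 0L]
  if (sort(labels)[1] %in% side) side <- setdiff(labels, side)
  paste(sort(side), collapse = ",")
}

# per-sample split-mask matrix and labels from the accepted input kinds
.sample_splits <- function(x, burnin) {
  if (inherits(x, "pgmcmc_run")) {
    ns <- nrow(x$samples)
    keep <- seq.int(floor(ns * burnin) + 1, ns)
    if (!length(keep)) stop("no post-burn-in samples")
    return(list(masks = x$splits[keep, , drop = FALSE], labels = x$labels))
  }
  trees <- if (inherits(x, "multiPhylo")) lapply(x, as_utree)
  else if (is.character(x) && length(x) == 1 && file.exists(x))
    lapply(read_tree_samples(x)$newick, read_newick)
  else if (is.character(x)) lapply(x, read_newick)
  else if (is.list(x)) lapply(x, as_utree)
  else stop("unsupported tree-sample input")
  ns <- length(trees)
  keep <- seq.int(floor(ns * burnin) + 1, ns)
  if (!length(keep)) stop("no post-burn-in samples")
  trees <- trees[keep]
  labels <- trees[[1]]$labels
  for (tr in trees) if (!setequal(tr$labels, labels))
    stop("inconsistent taxon sets across tree samples")
  masks <- t(vapply(trees, function(tr) {
    # map to the reference label order before masking
    perm <- match(tr$labels, labels)
    edge <- tr$edge
    tipsel <- edge <= tr$ntips
    edge[tipsel] <- perm[edge[tipsel]]
    sort(cpp_splits(tr$ntips, edge))
  }, integer(max(length(labels) - 3, 0))))
  if (length(labels) - 3 == 0) masks <- matrix(0L, length(trees), 0)
  list(masks = masks, labels = labels)
}

#' Sampled split (bipartition) frequencies
#'
#' Frequency of every nontrivial split among the retained (post-burn-in)
#' tree samples. Splits are written as the comma-separated taxon set on the
#' side not containing the alphabetically first taxon.
#'
#' @param x a `pgmcmc_run`, a character vector of Newick strings, a path to
#'   a `.trees` sample file, a `multiPhylo`, or a list of trees.
#' @param burnin fraction of samples to discard (default 0.25).
#' @return A data frame of class `split_table` with columns `split` and
#'   `freq`, and attributes `nsamples` and `taxa`.
#' @export
split_frequencies <- function(x, burnin = 0.25) {
  ss <- .sample_splits(x, burnin)
  ns <- nrow(ss$masks)
  tab <- table(as.vector(ss$masks))
  splits <- vapply(as.integer(names(tab)), .mask_to_split, "",
                   labels = ss$labels)
  out <- data.frame(split = splits, freq = as.numeric(tab) / ns)
  out <- out[order(-out$freq, out$split), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, nsamples = ns, taxa = sort(ss$labels), burnin = burnin,
            class = c("split_table", "data.frame"))
}

#' Average standard deviation of split frequencies (ASDSF)
#'
#' The convergence diagnostic compared across independent runs: over all
#' splits whose frequency reaches `min_freq` in at least one run, the
#' across-run standard deviation (denominator n-1) of the split frequency,
#' averaged over those splits. Identical runs give exactly 0; runs are
#' conventionally considered converged below about 0.02.
#'
#' @param ... two or more runs / split tables (any [split_frequencies]
#'   input).
#' @param min_freq inclusion threshold (default 0.10).
#' @param burnin burn-in fraction applied to raw inputs.
#' @return The ASDSF value.
#' @export
asdsf <- function(..., min_freq = 0.1, burnin = 0.25) {
  runs <- list(...)
  if (length(runs) == 1 && is.list(runs[[1]]) && !inherits(runs[[1]], "split_table") &&
      !inherits(runs[[1]], "pgmcmc_run"))
    runs <- runs[[1]]
  if (length(runs) < 2) stop("ASDSF needs at least two runs")
  tabs <- lapply(runs, function(r)
    if (inherits(r, "split_table")) r else split_frequencies(r, burnin))
  taxa <- attr(tabs[[1]], "taxa")
  for (tb in tabs) if (!identical(attr(tb, "taxa"), taxa))
    stop("runs cover different taxon sets")
  splits <- unique(unlist(lapply(tabs, function(tb) tb$split)))
  fm <- vapply(tabs, function(tb) {
    f <- tb$freq[match(splits, tb$split)]
    f[is.na(f)] <- 0
    f
  }, numeric(length(splits)))
  fm <- matrix(fm, nrow = length(splits))
  qual <- apply(fm, 1, max) >= min_freq
  if (!any(qual)) {
    warning("no split reaches min_freq in any run; ASDSF defined as 0")
    return(0)
  }
  mean(apply(fm[qual, , drop = FALSE], 1, stats::sd))
}

#' Posterior topology frequencies
#'
#' Tabulates the sampled topologies (after burn-in) by canonical topology
#' key; the keys match [topology_key] and [enumerate_topologies], so for
#' small taxon sets the result can be aligned against the full enumeration.
#'
#' @inheritParams split_frequencies
#' @return Named numeric vector of frequencies summing to 1.
#' @export
topology_posterior <- function(x, burnin = 0.25) {
  ss <- .sample_splits(x, burnin)
  ids <- apply(ss$masks, 1, paste, collapse = ",")
  if (!length(ids)) stop("no post-burn-in samples")
  tab <- table(ids)
  labels <- ss$labels
  keys <- vapply(names(tab), function(id) {
    masks <- as.integer(strsplit(id, ",", fixed = TRUE)[[1]])
    masks <- masks[!is.na(masks)]
    sp <- vapply(masks, .mask_to_split, "", labels = labels)
    paste0(paste(sort(labels), collapse = ","), "#",
           paste(sort(sp), collapse = ";"))
  }, "")
  out <- as.numeric(tab) / sum(tab)
  names(out) <- keys
  sort(out, decreasing = TRUE)
}
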