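#' Tuning parameters for the tree proposals
#'
#' Defaults follow the values used throughout the validation experiments:
#' extension probability \eqn{p_e = 0.5}; warp factors \eqn{\epsilon_1 = 0.5}
#' (scheme 1, constant base factor \eqn{e^{-1}}) and \eqn{\epsilon_2 = 0.1}
#' (scheme 2, JC69-derived base factor); pseudo-length offset
#' \eqn{\eta = 10^{-4}}; TBR reconnection radius \eqn{\delta = 5}; and the
#' branch-length scaler tuning \eqn{\lambda = 2\ln 1.05}, which bounds
#' proposed multipliers at 5\% up or down.
#'
#' @param pe extension probability in [0, 1).
#' @param eps1,eps2 warp factors (> 0) for schemes 1 and 2.
#' @param eta pseudo-length offset added to \eqn{S_i/N} (> 0).
#' @param rho_scheme base-factor constant for scheme 2: `"quarter"` uses
#'   \eqn{\rho = \frac14(1 - e^{-4\hat v/3})}, the JC69 probability of ending
#'   in one specific different state (this reproduces the reference example
#'   weights); `"threequarter"` uses the total change probability
#'   \eqn{\frac34(1 - e^{-4\hat v/3})}. Both are valid proposal
#'   distributions; the choice affects efficiency only.
#' @param delta TBR node radius (>= 1).
#' @param lambda_scale scaler tuning for branch lengths touched by tree
#'   moves.
#' @param lambda_brlen,lambda_treelen tunings of the stand-alone single
#'   branch scaler and the tree-length multiplier.
#' @return A list of class `move_tuning`.
#' @export
move_tuning <- function(pe = 0.5, eps1 = 0.5, eps2 = 0.1, eta = 1e-4,
                        rho_scheme = c("quarter", "threequarter"),
                        delta = 5L,
                        lambda_scale = 2 * log(1.05),
                        lambda_brlen = 2 * log(2),
                        lambda_treelen = 2 * log(1.1)) {
  rho_scheme <- match.arg(rho_scheme)
  stopifnot(pe >= 0, pe < 1, eps1 > 0, eps2 > 0, eta > 0, delta >= 1,
            lambda_scale > 0, lambda_brlen > 0, lambda_treelen > 0)
  structure(list(pe = pe, eps1 = eps1, eps2 = eps2, eta = eta,
                 rho_factor = if (rho_scheme == "quarter") 0.25 else 0.75,
                 rho_scheme = rho_scheme,
                 delta = as.integer(delta),
                 lam_scale = lambda_scale, lam_brlen = lambda_brlen,
                 lam_tl = lambda_treelen),
            class = "move_tuning")
}

.move_ids <- c(sNNI = 0L, eSPR = 1L, eTBR = 2L, pSPR1 = 3L, pSPR2 = 4L,
               pTBR1 = 5L, pTBR2 = 6L, brlen = 7L, treelen = 8L,
               alpha = 9L, exch = 10L, kappa = 11L)

#' Parsimony guide weights for regraft candidates
#'
#' The weight of proposing candidate branch *i* is
#' \eqn{\omega_i = \rho_i^{\epsilon S_i}}, where \eqn{S_i} is the candidate's
#' parsimony score, \eqn{\epsilon} the warp factor and \eqn{\rho_i} the base
#' factor: scheme 1 sets \eqn{\rho_i = e^{-1}} so that
#' \eqn{\omega_i = e^{-\epsilon_1 S_i}}; scheme 2 sets
#' \eqn{\rho_i = \frac14(1 - e^{-4\hat v_i/3})} with the quick branch-length
#' estimate \eqn{\hat v_i = S_i/N + \eta}, discounting the influence of high
#' scores on what is probably just a long branch. Log weights are shifted so
#' the minimum-score candidate has log-weight 0.
#'
#' @param scores numeric vector of candidate parsimony scores (e.g. from
#'   [regraft_scores]); names are preserved.
#' @param tuning a [move_tuning].
#' @param N total number of sites (required for scheme 2).
#' @param variant 1 or 2.
#' @param log return log weights instead of weights.
#' @return Numeric vector of (log) weights, minimum-score candidate at 1
#'   (or 0 on the log scale).
#' @examples
#' w <- guide_weights(10:16, move_tuning(), variant = 1)
#' round(w, 3)   # 1 0.607 0.368 0.223 0.135 0.082 0.050
#' @export
guide_weights <- function(scores, tuning = move_tuning(), N = NULL,
                          variant = 1, log = FALSE) {
  if (!length(scores)) stop("empty score set")
  if (variant == 1) {
    lw <- -tuning$eps1 * scores
  } else {
    if (is.null(N) || N <= 0) stop("scheme 2 needs the total site count N")
    vhat <- scores / N + tuning$eta
    rho <- tuning$rho_factor * (1 - exp(-4 * vhat / 3))
    lw <- tuning$eps2 * scores * base::log(rho)
  }
  lw <- lw - lw[which.min(scores)]
  names(lw) <- names(scores)
  if (log) lw else exp(lw)
}

#' Log Hastings ratio of a guided regraft selection
#'
#' For weights \eqn{\omega} over the remainder branch set \eqn{\mathcal B},
#' old attachment `b` and proposed attachment `r`, returns
#' \deqn{\log\frac{\omega_b / \sum_{i \in \mathcal B \setminus r} \omega_i}
#'                {\omega_r / \sum_{j \in \mathcal B \setminus b} \omega_j},}
#' evaluated stably in log space. The candidate excluded from each sum is
#' the respective target (the move is Metropolized: the current attachment
#' can never be proposed).
#'
#' @param logw named or plain numeric vector of log weights over
#'   \eqn{\mathcal B}.
#' @param b,r indices (or names) of the old and proposed attachment; must
#'   differ.
#' @return Log Hastings ratio (finite numeric).
#' @export
log_hastings_guided <- function(logw, b, r) {
  if (is.character(b)) b <- match(b, names(logw))
  if (is.character(r)) r <- match(r, names(logw))
  if (is.na(b) || is.na(r) || b < 1 || r < 1 || b > length(logw) || r > length(logw))
    stop("b and r must index the weight vector")
  if (b == r) stop("contract violation: b and r must differ")
  lse <- function(x) { m <- max(x); m + base::log(sum(exp(x - m))) }
  (logw[[b]] - lse(logw[-r])) - (logw[[r]] - lse(logw[-b]))
}

#' Draw tree proposals
#'
#' Runs the requested move (stochastic NNI; extending SPR/TBR; or the
#' parsimony-guided pSPR/pTBR in either weighting scheme) from the given
#' tree, returning the proposed tree and the exact log Hastings ratio
#' (topology-selection term plus one log-multiplier per rescaled branch).
#' All moves are Metropolized: the proposed topology always differs from the
#' current one.
#'
#' @param tree a [utree] (n >= 4; eTBR/pTBR need n >= 5).
#' @param move one of `"sNNI"`, `"eSPR"`, `"eTBR"`, `"pSPR1"`, `"pSPR2"`,
#'   `"pTBR1"`, `"pTBR2"`.
#' @param tuning a [move_tuning].
#' @param data optional [pattern_matrix] providing parsimony guidance for
#'   the pSPR/pTBR moves (without it all candidate scores are 0 and the
#'   selection is uniform).
#' @param n number of independent proposals to draw from this tree.
#' @param seed integer seed for the proposal RNG (defaults to a draw from
#'   R's RNG, so results are reproducible under [set.seed]).
#' @param keep_trees how many proposed trees to materialise as [utree]
#'   objects (diagnostics vectors are always returned for all `n`).
#' @return For `n = 1` a `proposal` list with elements `tree`,
#'   `log_hastings`, `log_hastings_topology`, `branches` (the picked branch
#'   `a`, bridge `b`, pendant `q`, regraft `r`) and mechanism diagnostics;
#'   for `n > 1` a list with vectors and a `trees` list.
#' @export
propose_move <- function(tree, move, tuning = move_tuning(), data = NULL,
                         n = 1, seed = NULL, keep_trees = n) {
  tree <- as_utree(tree)
  mv <- .move_ids[[match.arg(move, names(.move_ids)[1:7])]]
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  guide <- if (!is.null(data)) .pm_for_tree(pattern_matrix(data), tree) else NULL
  res <- cpp_propose_batch(tree$ntips, tree$edge, tree$length, mv,
                           unclass(tuning), guide, seed, as.integer(n),
                           as.integer(min(keep_trees, n)))
  mk <- function(tl) utree(tl$edge, tl$length, tree$labels)
  if (n == 1) {
    return(structure(list(tree = mk(res$trees[[1]]),
                          log_hastings = res$logH[1],
                          log_hastings_topology = res$logH_topo[1],
                          branches = c(a = res$a[1], b = res$b[1],
                                       q = res$q[1], r = res$r[1]),
                          distance = res$d1[1],
                          moved_second_end = res$moved2[1],
                          first_edge_interior = res$first_internal[1],
                          constrained = c(forward = res$fwd_constrained[1],
                                          backward = res$rev_constrained[1])),
                     class = "proposal"))
  }
  res$trees <- lapply(res$trees[seq_len(min(keep_trees, n))], mk)
  res
}

#' @export
print.proposal <- function(x, ...) {
  cat("tree proposal: log Hastings", format(x$log_hastings, digits = 6),
      "(topology part", format(x$log_hastings_topology, digits = 6), ")\n")
  cat("branches a/b/q/r:", paste(x$branches, collapse = "/"),
      " distance:", x$distance, "\n")
  invisible(x)
}

#' Branch-length scaler move
#'
#' Proposes \eqn{v' = v\,e^{\lambda(u - 1/2)}} with \eqn{u \sim U(0,1)};
#' the Hastings contribution is \eqn{\log m}. With the default
#' \eqn{\lambda = 2\ln 1.05} the multiplier is bounded in
#' \eqn{[1/1.05,\ 1.05]}: at most 5\% up or down.
#'
#' @param v current branch length (> 0).
#' @param lambda scaler tuning (> 0).
#' @param u optional uniform draw (defaults to `runif(1)`).
#' @return List with `value` (the proposed length) and `log_hastings`.
#' @export
scale_branch <- function(v, lambda = 2 * log(1.05), u = stats::runif(1)) {
  if (v <= 0) stop("the scaler is undefined at branch length 0")
  if (lambda <= 0) stop("lambda must be > 0")
  m <- exp(lambda * (u - 0.5))
  list(value = v * m, log_hastings = log(m))
}
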