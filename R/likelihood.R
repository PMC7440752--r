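#' Substitution model specification
#'
#' JC69, K80 (transition/transversion parameter `kappa`) or GTR
#' (exchangeabilities and stationary frequencies), optionally with
#' discrete-gamma rate variation across sites (`gamma_categories` equal-
#' probability categories with mean category rates, shape `alpha`). The rate
#' matrix is scaled to one expected substitution per site per unit branch
#' length, and the category rates average to 1.
#'
#' @param model `"JC69"`, `"K80"` or `"GTR"`.
#' @param kappa K80 transition/transversion rate ratio (> 0).
#' @param exch six GTR exchangeabilities (order AC, AG, AT, CG, CT, GT);
#'   normalised to sum to 1.
#' @param pi stationary base frequencies (A, C, G, T); normalised to sum
#'   to 1.
#' @param gamma_categories number of discrete gamma categories (1 = no rate
#'   variation).
#' @param alpha gamma shape (> 0).
#' @return An object of class `subst_model`.
#' @examples
#' subst_model("K80", kappa = 4)
#' subst_model("GTR", gamma_categories = 4, alpha = 0.5)
#' @export
subst_model <- function(model = c("JC69", "K80", "GTR"), kappa = 1,
                        exch = rep(1 / 6, 6), pi = rep(0.25, 4),
                        gamma_categories = 1L, alpha = 1) {
  model <- match.arg(model)
  stopifnot(kappa > 0, length(exch) == 6, all(exch > 0),
            length(pi) == 4, all(pi > 0), gamma_categories >= 1, alpha > 0)
  structure(list(id = model, kappa = kappa,
                 exch = exch / sum(exch), pi = pi / sum(pi),
                 ncat = as.integer(gamma_categories), alpha = alpha),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(x$id,
      if (x$id == "K80") paste0("(kappa = ", x$kappa, ")") else "",
      if (x$ncat > 1) paste0("+ Gamma", x$ncat, " (alpha = ", x$alpha, ")") else "",
      "\n")
  invisible(x)
}

.model_list <- function(m) {
  list(id = m$id, kappa = m$kappa, exch = m$exch, pi = m$pi,
       ncat = m$ncat, alpha = m$alpha)
}

#' Discrete gamma category rates
#'
#' Mean rates of `ncat` equal-probability categories of a Gamma(alpha,
#' alpha) distribution (mean 1).
#'
#' @param alpha gamma shape.
#' @param ncat number of categories.
#' @return Numeric vector of rates averaging 1.
#' @export
gamma_category_rates <- function(alpha, ncat) {
  if (ncat == 1) return(1)
  q <- stats::qgamma(seq_len(ncat - 1) / ncat, shape = alpha, rate = alpha)
  p1 <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  ncat * diff(p1)
}

#' Transition probability matrix
#'
#' \eqn{P(v r)} for the model; closed forms for JC69 and K80, spectral
#' decomposition of the symmetrised rate matrix for GTR. Rows sum to 1 and
#' `v = 0` gives the identity.
#'
#' @param model a [subst_model].
#' @param v branch length (expected substitutions/site, >= 0).
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @return 4x4 stochastic matrix (rows/cols A, C, G, T).
#' @export
transition_matrix <- function(model, v, rate = 1) {
  if (v < 0) stop("branch length must be >= 0")
  t <- v * rate
  states <- c("A", "C", "G", "T")
  if (model$id == "JC69") {
    e <- exp(-4 * t / 3)
    P <- matrix(0.25 - 0.25 * e, 4, 4)
    diag(P) <- 0.25 + 0.75 * e
  } else if (model$id == "K80") {
    k <- model$kappa
    beta <- 1 / (k + 2)
    e1 <- exp(-4 * beta * t)
    e2 <- exp(-2 * beta * (k + 1) * t)
    ps <- 0.25 + 0.25 * e1 + 0.5 * e2
    pts <- 0.25 + 0.25 * e1 - 0.5 * e2
    ptv <- 0.25 - 0.25 * e1
    P <- matrix(ptv, 4, 4)
    P[cbind(c(1, 3, 2, 4), c(3, 1, 4, 2))] <- pts   # A<->G, C<->T
    diag(P) <- ps
  } else {
    pi <- model$pi
    Q <- matrix(0, 4, 4)
    Q[lower.tri(Q)] <- 0   # fill symmetric pattern explicitly
    idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (k in seq_len(6)) {
      i <- idx[k, 1]; j <- idx[k, 2]
      Q[i, j] <- model$exch[k] * pi[j]
      Q[j, i] <- model$exch[k] * pi[i]
    }
    diag(Q) <- -rowSums(Q)
    mu <- -sum(pi * diag(Q))
    Q <- Q / mu
    S <- diag(sqrt(pi)) %*% Q %*% diag(1 / sqrt(pi))
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
    P <- diag(1 / sqrt(pi)) %*% ev$vectors %*% diag(exp(ev$values * t)) %*%
      t(ev$vectors) %*% diag(sqrt(pi))
    P[P < 0] <- 0
  }
  dimnames(P) <- list(states, states)
  P
}

#' Log likelihood by the pruning algorithm
#'
#' Felsenstein pruning over the compressed site patterns with per-node
#' rescaling to protect against underflow; the result is invariant to where
#' the traversal is rooted. Gamma rate variation is integrated over the
#' discrete categories.
#'
#' @param tree a [utree].
#' @param data a [pattern_matrix] covering the tree's taxa.
#' @param model a [subst_model].
#' @return The log likelihood (finite numeric; an error is raised
#'   otherwise).
#' @export
log_likelihood <- function(tree, data, model) {
  tree <- as_utree(tree)
  cpp_loglik(tree$ntips, tree$edge, tree$length,
             .pm_for_tree(pattern_matrix(data), tree), .model_list(model))
}
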