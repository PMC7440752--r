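#' Prior configuration
#'
#' The topology prior is uniform over unrooted binary topologies (it
#' contributes a constant that cancels in every acceptance ratio). Branch
#' lengths follow either i.i.d. exponentials or the compound gamma-Dirichlet
#' prior: the tree length \eqn{T = \sum_b v_b} is Gamma(`a_T`, rate `b_T`)
#' and, given \eqn{T}, the branch proportions are Dirichlet with
#' concentration `a_c` on external and `a_c * c` on internal branches
#' (`c = 1` is symmetric). The default gamma-Dirichlet(1, 0.1, 1, 1) gives
#' mean tree length 10. The gamma shape gets an Exponential prior, as does
#' kappa when it is sampled; GTR exchangeabilities get a flat Dirichlet.
#'
#' @param brlen `"gammadir"` or `"exponential"`.
#' @param gd gamma-Dirichlet hyperparameters `c(a_T, b_T, a_c, c)`; `b_T`
#'   is a rate.
#' @param exp_rate rate of the exponential branch-length prior.
#' @param alpha_rate rate of the Exponential prior on the gamma shape.
#' @param kappa_rate rate of the Exponential prior on kappa.
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(brlen = c("gammadir", "exponential"),
                         gd = c(1, 0.1, 1, 1), exp_rate = 10,
                         alpha_rate = 1, kappa_rate = 0.1) {
  brlen <- match.arg(brlen)
  stopifnot(length(gd) == 4, all(gd > 0), exp_rate > 0,
            alpha_rate > 0, kappa_rate > 0)
  structure(list(brlen = brlen, gd = as.numeric(gd), exp_rate = exp_rate,
                 alpha_rate = alpha_rate, kappa_rate = kappa_rate),
            class = "prior_config")
}

.prior_list <- function(p) unclass(p)

#' Log prior density of a chain state
#'
#' Sums the branch-length log density (including the Jacobian of the
#' `(v) -> (T, proportions)` change of variables for the gamma-Dirichlet
#' prior), the Exponential log density of the gamma shape and of kappa when
#' those are sampled, and the (constant) flat-Dirichlet term for GTR
#' exchangeabilities. States outside the support return `-Inf` rather than
#' raising an error.
#'
#' @param state a [utree], or a list with elements `tree` and optionally
#'   `model` (a [subst_model]) plus logical flags `sample_alpha`,
#'   `sample_kappa`.
#' @param config a [prior_config].
#' @return Log prior density (may be `-Inf`).
#' @export
log_prior <- function(state, config = prior_config()) {
  if (inherits(state, "utree")) state <- list(tree = state)
  tree <- as_utree(state$tree)
  if (any(state$tree$length < 0)) return(-Inf)
  lp <- cpp_log_prior_brlen(tree$ntips, tree$edge, tree$length,
                            .prior_list(config))
  m <- state$model
  if (!is.null(m)) {
    if (isTRUE(state$sample_alpha)) {
      if (m$alpha <= 0) return(-Inf)
      lp <- lp + stats::dexp(m$alpha, config$alpha_rate, log = TRUE)
    }
    if (isTRUE(state$sample_kappa)) {
      if (m$kappa <= 0) return(-Inf)
      lp <- lp + stats::dexp(m$kappa, config$kappa_rate, log = TRUE)
    }
  }
  lp
}
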