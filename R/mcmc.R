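#' Move schedules and the standard presets
#'
#' A schedule is a data frame of `(move, weight)` rows; one move is drawn
#' per generation with probability proportional to its weight. Presets:
#'
#' * `"simulation"` — the prior-recovery protocol: one tree proposal
#'   (`tree_move`) and the branch-length scaler at a 5:1 ratio.
#' * `"reference"` — the reference-run mix 1 sNNI : 2 eSPR : 1 eTBR :
#'   2 pSPR2 : 1 pTBR2 with category masses 46.67\% tree, 50\% branch
#'   length, 3.33\% substitution parameters.
#' * `"test"` — the single-chain evaluation runs: a tree-move mix
#'   (`"eSPR+eTBR"`, `"pSPR1+pTBR1"` or `"pSPR2+pTBR2"`, each 2:1) at 36\%,
#'   branch lengths 60\%, substitution parameters 4\%.
#'
#' Within the branch-length mass the single-branch scaler and the
#' tree-length multiplier split 4:1; the substitution mass is divided evenly
#' among the model's free parameters (and folded into the branch-length
#' mass when there are none).
#'
#' @param preset `"simulation"`, `"reference"` or `"test"`.
#' @param tree_move tree proposal for the `"simulation"` preset.
#' @param mix tree-move mix for the `"test"` preset.
#' @param model a [subst_model], used to decide which substitution-parameter
#'   moves apply (gamma shape when `gamma_categories > 1`, kappa for K80,
#'   exchangeabilities for GTR).
#' @return A data frame with columns `move` and `weight`.
#' @export
schedule_preset <- function(preset = c("simulation", "reference", "test"),
                            tree_move = "pSPR2",
                            mix = c("eSPR+eTBR", "pSPR1+pTBR1", "pSPR2+pTBR2"),
                            model = subst_model()) {
  preset <- match.arg(preset)
  subst <- c(if (model$ncat > 1) "alpha",
             if (model$id == "K80") "kappa",
             if (model$id == "GTR") "exch")
  if (preset == "simulation") {
    tree_move <- match.arg(tree_move, names(.move_ids)[1:7])
    return(data.frame(move = c(tree_move, "brlen"), weight = c(5, 1)))
  }
  if (preset == "reference") {
    tree <- data.frame(move = c("sNNI", "eSPR", "eTBR", "pSPR2", "pTBR2"),
                       weight = c(1, 2, 1, 2, 1) / 7 * 46.67)
    bl_mass <- 50 + if (length(subst)) 0 else 3.33
    bl <- data.frame(move = c("brlen", "treelen"), weight = c(0.8, 0.2) * bl_mass)
    sp <- if (length(subst))
      data.frame(move = subst, weight = rep(3.33 / length(subst), length(subst)))
    else NULL
    return(rbind(tree, bl, sp))
  }
  mix <- match.arg(mix)
  mv <- strsplit(mix, "+", fixed = TRUE)[[1]]
  tree <- data.frame(move = mv, weight = c(2, 1) / 3 * 36)
  bl_mass <- 60 + if (length(subst)) 0 else 4
  bl <- data.frame(move = c("brlen", "treelen"), weight = c(0.8, 0.2) * bl_mass)
  sp <- if (length(subst))
    data.frame(move = subst, weight = rep(4 / length(subst), length(subst)))
  else NULL
  rbind(tree, bl, sp)
}

.check_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule), all(c("move", "weight") %in% names(schedule)))
  bad <- setdiff(schedule$move, names(.move_ids))
  if (length(bad)) stop("unknown moves in schedule: ", paste(bad, collapse = ", "))
  if (any(schedule$weight <= 0)) stop("schedule weights must be > 0")
  schedule
}

#' Run the Metropolis(-coupled) sampler
#'
#' One move is drawn from the schedule per generation; proposals are
#' accepted with probability \eqn{\min(1, e^{\beta\,\Delta\log L +
#' \Delta\log \pi + \log H})}. With `nchains > 1`, Metropolis coupling runs
#' heated chains at \eqn{\beta_i = 1/(1 + \lambda_h i)} with one random-pair
#' swap attempt per generation; only the cold chain is sampled. Runs are
#' bit-reproducible given `seed`.
#'
#' The guided moves take their parsimony scores from `guide_data`
#' (defaulting to `data`); `guide_sites = m` restricts the guidance to the
#' first *m* alignment columns. Setting `constant_likelihood = TRUE` fixes
#' the likelihood at zero, which samples the prior — combined with guidance
#' this is the misleading-weights experiment that exercises the Hastings
#' correction.
#'
#' @param tree starting [utree]; or `NULL` to start from a random topology
#'   (all branch lengths 0.1) over `taxa` or the data's taxa.
#' @param taxa tip labels (or a count) when no tree and no data are given.
#' @param data alignment for the likelihood ([pattern_matrix] or character
#'   matrix); `NULL` implies `constant_likelihood`.
#' @param model a [subst_model].
#' @param prior a [prior_config].
#' @param schedule a move schedule (see [schedule_preset]).
#' @param generations number of MCMC generations.
#' @param sample_every sampling interval in generations.
#' @param nchains number of Metropolis-coupled chains.
#' @param heat_lambda heating increment \eqn{\lambda_h}.
#' @param seed integer seed controlling every source of randomness.
#' @param constant_likelihood fix the likelihood at zero (prior sampling).
#' @param guide_data alignment for parsimony guidance (defaults to `data`).
#' @param guide_sites use only the first `guide_sites` columns for guidance.
#' @param tuning a [move_tuning].
#' @param hastings internal switch for the negative-control experiment;
#'   `FALSE` drops the topology-selection Hastings term of guided moves.
#' @param sample_alpha,sample_kappa,sample_exch whether those model
#'   parameters are sampled (defaults: whenever the schedule contains the
#'   corresponding move).
#' @return An object of class `pgmcmc_run`: a list with `samples` (data
#'   frame: generation, log likelihood, log prior, tree length), `newick`
#'   (one sampled tree per row), `splits` (canonical split masks per
#'   sample), `acceptance` (per-move counts), the final state and the full
#'   configuration echo.
#' @export
mcmc_run <- function(tree = NULL, taxa = NULL, data = NULL,
                     model = subst_model(), prior = prior_config(),
                     schedule = schedule_preset("simulation", "pSPR2"),
                     generations, sample_every = 100, nchains = 1,
                     heat_lambda = 0.1, seed = 1,
                     constant_likelihood = is.null(data),
                     guide_data = NULL, guide_sites = NULL,
                     tuning = move_tuning(), hastings = TRUE,
                     sample_alpha = "alpha" %in% schedule$move,
                     sample_kappa = "kappa" %in% schedule$move,
                     sample_exch = "exch" %in% schedule$move) {
  schedule <- .check_schedule(schedule)
  if (!is.null(data)) data <- pattern_matrix(data)
  if (is.null(guide_data)) guide_data <- data
  if (!is.null(guide_data) && !is.null(guide_sites)) {
    aln <- attr(guide_data, "alignment")
    if (is.null(aln) && is.matrix(guide_data)) aln <- guide_data
    if (is.null(aln))
      stop("guide_sites needs the uncompressed alignment ",
           "(read_alignment keeps it; or pass a character matrix)")
    guide_data <- pattern_matrix(aln[, seq_len(guide_sites), drop = FALSE])
  }
  if (!is.null(guide_data)) guide_data <- pattern_matrix(guide_data)
  set.seed(seed)
  if (is.null(tree)) {
    if (is.null(taxa)) {
      if (is.null(data) && is.null(guide_data))
        stop("give a starting tree, taxa, or data")
      taxa <- if (!is.null(data)) data$taxa else guide_data$taxa
    }
    tree <- random_utree(taxa)
  }
  tree <- as_utree(tree)
  if (!constant_likelihood && is.null(data))
    stop("likelihood sampling requires data")
  if (any(c("pSPR1", "pSPR2", "pTBR1", "pTBR2") %in% schedule$move) &&
      is.null(guide_data) && !constant_likelihood)
    stop("parsimony-guided moves need guide data")
  cfg <- list(
    ntips = tree$ntips, edge = tree$edge, length = tree$length,
    labels = tree$labels,
    use_likelihood = !constant_likelihood,
    hastings_on = hastings,
    data = if (!constant_likelihood) .pm_for_tree(data, tree) else NULL,
    guide = if (!is.null(guide_data)) .pm_for_tree(guide_data, tree) else NULL,
    model = .model_list(model), prior = .prior_list(prior),
    tuning = unclass(tuning),
    schedule_moves = .move_ids[schedule$move],
    schedule_weights = schedule$weight,
    generations = as.numeric(generations),
    sample_every = as.integer(sample_every),
    nchains = as.integer(nchains), heat_lambda = heat_lambda,
    seed = as.numeric(seed),
    sample_alpha = sample_alpha, sample_kappa = sample_kappa,
    sample_exch = sample_exch)
  res <- cpp_mcmc_run(cfg)
  acc <- data.frame(move = names(.move_ids),
                    proposed = res$proposed, accepted = res$accepted)
  acc <- acc[acc$proposed > 0, , drop = FALSE]
  acc$p_accept <- acc$accepted / acc$proposed
  structure(list(
    samples = data.frame(gen = res$gen, logL = res$logL, logPr = res$logPr,
                         tree_length = res$tree_length),
    newick = res$newick, splits = res$splits, labels = tree$labels,
    acceptance = acc,
    swaps = c(proposed = res$swap_proposed, accepted = res$swap_accepted),
    final = res$final, seed = seed,
    config = list(schedule = schedule, model = model, prior = prior,
                  tuning = tuning, generations = generations,
                  sample_every = sample_every, nchains = nchains,
                  heat_lambda = heat_lambda,
                  constant_likelihood = constant_likelihood,
                  guide_sites = guide_sites, hastings = hastings)),
    class = "pgmcmc_run")
}

#' @export
print.pgmcmc_run <- function(x, ...) {
  n <- nrow(x$samples)
  cat("MCMC run:", format(x$config$generations, big.mark = ","),
      "generations,", n, "samples,", length(x$labels), "taxa\n")
  cat("overall acceptance:",
      sprintf("%.1f%%", 100 * sum(x$acceptance$accepted) / sum(x$acceptance$proposed)),
      "\n")
  print(x$acceptance, row.names = FALSE)
  invisible(x)
}

#' Write run output files
#'
#' `prefix.trees` holds one sampled tree per line, as a generation-number
#' column and a Newick string separated by a tab; `prefix.trace.tsv` the
#' scalar trace; `prefix.log` a configuration echo including the seed.
#'
#' @param run a `pgmcmc_run`.
#' @param prefix output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_run <- function(run, prefix) {
  tf <- paste0(prefix, ".trees")
  writeLines(paste(run$samples$gen, run$newick, sep = "\t"), tf)
  trf <- paste0(prefix, ".trace.tsv")
  utils::write.table(run$samples, trf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lf <- paste0(prefix, ".log")
  cfg <- run$config
  writeLines(c(
    paste("seed:", run$seed),
    paste("generations:", cfg$generations),
    paste("sample_every:", cfg$sample_every),
    paste("chains:", cfg$nchains, "heat_lambda:", cfg$heat_lambda),
    paste("constant_likelihood:", cfg$constant_likelihood),
    paste("model:", cfg$model$id),
    paste("schedule:", paste(sprintf("%s=%g", cfg$schedule$move,
                                     cfg$schedule$weight), collapse = " "))),
    lf)
  invisible(c(trees = tf, trace = trf, log = lf))
}

#' Read a tree-sample file written by [write_run]
#'
#' @param file path to a `.trees` file.
#' @return List with `gen` and `newick` vectors.
#' @export
read_tree_samples <- function(file) {
  ln <- readLines(file)
  parts <- strsplit(ln, "\t", fixed = TRUE)
  list(gen = as.numeric(vapply(parts, `[`, "", 1)),
       newick = vapply(parts, `[`, "", 2))
}

#' Initialise a chain state
#'
#' Bundles a tree and model with their cached log prior and log likelihood
#' for use with [mh_step].
#'
#' @param tree a [utree].
#' @param model a [subst_model].
#' @param prior a [prior_config].
#' @param data alignment, or `NULL` for constant likelihood.
#' @param beta chain temperature in (0, 1]; 1 is the cold chain.
#' @return A list of class `chain_state`.
#' @export
chain_state <- function(tree, model = subst_model(), prior = prior_config(),
                        data = NULL, beta = 1) {
  tree <- as_utree(tree)
  logL <- if (is.null(data)) 0 else log_likelihood(tree, data, model)
  structure(list(tree = tree, model = model, prior = prior,
                 data = if (!is.null(data)) pattern_matrix(data) else NULL,
                 beta = beta,
                 logL = logL,
                 logPr = log_prior(list(tree = tree, model = model), prior)),
            class = "chain_state")
}

#' One Metropolis–Hastings step
#'
#' Reference (R-level) implementation of a single update: propose with the
#' given move, accept with probability
#' \eqn{\min(1, e^{\beta\,\Delta\log L + \Delta\log\pi + \log H})}.
#' Non-finite proposed log likelihoods auto-reject with a warning. Uses R's
#' RNG.
#'
#' @param state a [chain_state].
#' @param move a tree move name, `"brlen"` or `"treelen"`.
#' @param tuning a [move_tuning].
#' @param guide_data alignment for parsimony guidance (defaults to the
#'   state's data).
#' @return List with the (possibly updated) `state` and logical `accepted`.
#' @export
mh_step <- function(state, move, tuning = move_tuning(),
                    guide_data = state$data) {
  stopifnot(inherits(state, "chain_state"))
  tree <- state$tree
  if (move %in% names(.move_ids)[1:7]) {
    pr <- propose_move(tree, move, tuning, data = guide_data)
    newtree <- pr$tree
    logH <- pr$log_hastings
  } else if (move == "brlen") {
    e <- sample.int(nrow(tree$edge), 1)
    sc <- scale_branch(tree$length[e], tuning$lam_brlen)
    newtree <- tree
    newtree$length[e] <- sc$value
    logH <- sc$log_hastings
  } else if (move == "treelen") {
    m <- exp(tuning$lam_tl * (stats::runif(1) - 0.5))
    newtree <- tree
    newtree$length <- tree$length * m
    logH <- nrow(tree$edge) * log(m)
  } else stop("unknown move: ", move)
  newPr <- log_prior(list(tree = newtree, model = state$model), state$prior)
  newL <- if (is.null(state$data)) 0
          else log_likelihood(newtree, state$data, state$model)
  if (!is.finite(newL)) {
    warning("non-finite proposed log likelihood; proposal rejected")
    return(list(state = state, accepted = FALSE))
  }
  lr <- state$beta * (newL - state$logL) + (newPr - state$logPr) + logH
  accepted <- is.finite(newPr) && (log(stats::runif(1)) < lr)
  if (accepted) {
    state$tree <- newtree
    state$logL <- newL
    state$logPr <- newPr
  }
  list(state = state, accepted = accepted)
}
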