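#' Build and validate a run configuration
#'
#' A run configuration bundles everything [run_from_config] needs: the data
#' mode (`"data"` for likelihood-based sampling, `"nodata"` for the
#' constant-likelihood prior-sampling experiments), paths, model and prior
#' settings, a schedule preset or explicit weights, and the chain settings.
#' All validation problems are reported together in a single error.
#'
#' @param x a named list of settings, or a path to a YAML file holding one.
#' @param ... settings overriding those in `x`.
#' @return The validated configuration, class `run_config`.
#' @export
run_config <- function(x = list(), ...) {
  if (is.character(x) && length(x) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading configuration files requires the yaml package")
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  x <- utils::modifyList(x, list(...))
  defaults <- list(mode = if (is.null(x$data)) "nodata" else "data",
                   data = NULL, taxa = NULL, usedsites = NULL,
                   model = list(id = "JC69"),
                   prior = list(brlen = "gammadir", gd = c(1, 0.1, 1, 1)),
                   schedule = list(preset = "simulation", tree_move = "pSPR2"),
                   generations = 100000, sample_every = 100, burnin = 0.25,
                   seed = 1, chains = 1, heat_lambda = 0.1,
                   start_tree = NULL, out = NULL, hastings = TRUE)
  cfg <- utils::modifyList(defaults, x)
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  if (!cfg$mode %in% c("data", "nodata")) push("mode must be 'data' or 'nodata'")
  if (cfg$mode == "data" && is.null(cfg$data)) push("mode 'data' needs a data path")
  if (cfg$mode == "nodata" && is.null(cfg$data) && is.null(cfg$taxa) &&
      is.null(cfg$start_tree))
    push("mode 'nodata' needs 'taxa', 'start_tree' or 'data' (for guidance)")
  if (!is.null(cfg$data) && is.character(cfg$data) && !file.exists(cfg$data))
    push(paste("data file not found:", cfg$data))
  if (!is.null(cfg$start_tree) && is.character(cfg$start_tree) &&
      !file.exists(cfg$start_tree))
    push(paste("start tree file not found:", cfg$start_tree))
  if (!is.numeric(cfg$generations) || cfg$generations < 1)
    push("generations must be a positive number")
  if (!is.numeric(cfg$sample_every) || cfg$sample_every < 1)
    push("sample_every must be a positive number")
  if (!is.numeric(cfg$burnin) || cfg$burnin < 0 || cfg$burnin >= 1)
    push("burnin must be in [0, 1)")
  if (!is.numeric(cfg$seed)) push("seed must be numeric")
  if (!is.numeric(cfg$chains) || cfg$chains < 1) push("chains must be >= 1")
  if (!is.numeric(cfg$heat_lambda) || cfg$heat_lambda < 0)
    push("heat_lambda must be >= 0")
  if (!is.null(cfg$usedsites) &&
      (!is.numeric(cfg$usedsites) || cfg$usedsites < 0))
    push("usedsites must be a nonnegative number")
  if (!is.null(cfg$model$id) && !cfg$model$id %in% c("JC69", "K80", "GTR"))
    push("model id must be JC69, K80 or GTR")
  if (!is.null(cfg$schedule$preset) &&
      !cfg$schedule$preset %in% c("simulation", "reference", "test", "custom"))
    push("schedule preset must be simulation, reference, test or custom")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

.cfg_model <- function(cfg, data = NULL) {
  m <- cfg$model
  freq <- m$frequencies
  pi <- rep(0.25, 4)
  if (!is.null(freq) && identical(freq, "empirical")) {
    if (is.null(data)) stop("empirical frequencies need data")
    pi <- empirical_frequencies(data)
  } else if (is.numeric(freq)) pi <- freq
  subst_model(model = if (is.null(m$id)) "JC69" else m$id,
              kappa = if (is.null(m$kappa)) 1 else m$kappa,
              exch = if (is.null(m$exch)) rep(1 / 6, 6) else unlist(m$exch),
              pi = pi,
              gamma_categories = if (is.null(m$gamma_categories)) 1L
                                 else as.integer(m$gamma_categories),
              alpha = if (is.null(m$alpha)) 1 else m$alpha)
}

.cfg_prior <- function(cfg) {
  p <- cfg$prior
  prior_config(brlen = if (is.null(p$brlen)) "gammadir" else p$brlen,
               gd = if (is.null(p$gd)) c(1, 0.1, 1, 1) else unlist(p$gd),
               exp_rate = if (is.null(p$exp_rate)) 10 else p$exp_rate,
               alpha_rate = if (is.null(p$alpha_rate)) 1 else p$alpha_rate,
               kappa_rate = if (is.null(p$kappa_rate)) 0.1 else p$kappa_rate)
}

.cfg_schedule <- function(cfg, model) {
  s <- cfg$schedule
  if (identical(s$preset, "custom") || (is.null(s$preset) && !is.null(s$moves))) {
    mv <- s$moves
    return(data.frame(move = vapply(mv, function(z) z$move, ""),
                      weight = vapply(mv, function(z) as.numeric(z$weight), 0)))
  }
  if (identical(s$preset, "simulation"))
    return(schedule_preset("simulation", tree_move = s$tree_move %||% "pSPR2"))
  if (identical(s$preset, "reference"))
    return(schedule_preset("reference", model = model))
  schedule_preset("test", mix = s$mix %||% "pSPR2+pTBR2", model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a validated run configuration
#'
#' Loads data and starting tree as configured, assembles model, prior and
#' schedule, runs [mcmc_run] and (when `out` is set) writes the sample
#' files via [write_run].
#'
#' @param cfg a [run_config] (or anything it accepts).
#' @return The `pgmcmc_run`, invisibly when writing output files.
#' @export
run_from_config <- function(cfg) {
  cfg <- run_config(cfg)
  data <- NULL
  if (!is.null(cfg$data))
    data <- if (is.character(cfg$data)) read_alignment(cfg$data)
            else pattern_matrix(cfg$data)
  model <- .cfg_model(cfg, data)
  prior <- .cfg_prior(cfg)
  schedule <- .cfg_schedule(cfg, model)
  tree <- NULL
  if (!is.null(cfg$start_tree))
    tree <- if (is.character(cfg$start_tree)) read_newick(file = cfg$start_tree)
            else as_utree(cfg$start_tree)
  constant <- cfg$mode == "nodata"
  taxa <- cfg$taxa
  if (is.numeric(taxa) && length(taxa) == 1) taxa <- paste0("t", seq_len(taxa))
  guide_sites <- cfg$usedsites
  guide_data <- data
  if (!is.null(guide_sites) && guide_sites == 0) {
    guide_data <- NULL
    guide_sites <- NULL
  }
  run <- mcmc_run(tree = tree, taxa = taxa,
                  data = if (constant) NULL else data,
                  model = model, prior = prior, schedule = schedule,
                  generations = cfg$generations,
                  sample_every = cfg$sample_every,
                  nchains = cfg$chains, heat_lambda = cfg$heat_lambda,
                  seed = cfg$seed, constant_likelihood = constant,
                  guide_data = guide_data, guide_sites = guide_sites,
                  hastings = cfg$hastings)
  if (!is.null(cfg$out)) {
    write_run(run, cfg$out)
    return(invisible(run))
  }
  run
}
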