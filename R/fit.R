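#' Fitting configuration
#'
#' Settings for the derivative-free (Nelder--Mead simplex) fits.
#' Defaults: unconstrained search in log-parameter space (which enforces
#' positivity), objective relative tolerance 1e-8, at most 5000
#' iterations, 3 restarts with 10% log-space jitter around the supplied
#' initialization.  Bound-constrained fits (the hybrid model) search a
#' smooth sin^2 reparametrization of the box, so no candidate is ever
#' evaluated outside the bounds.
#'
#' @param train_conditions Optional list of [inducer_condition()]; when
#'   given, fitting uses only the matching entries of the data.  The
#'   default RNA-only split is [rna_only_train_conditions()].
#' @param transform `"log"` (default) or `"linear"` parameter space.
#' @param bounds Optional named list of `c(lo, hi)` per free parameter
#'   (required by [fit_hybrid()]); `lo == hi` pins a parameter.
#' @param max_iterations Simplex iteration cap per restart.
#' @param n_restarts Number of restarts (best result returned).
#' @param restart_jitter Log-space half-width of the restart jitter
#'   (fraction, default 0.1).
#' @param reltol Relative convergence tolerance on the objective.
#' @param seed RNG seed for the restart jitter.
#' @param weights `"none"` (default, unweighted SSE on replicate means)
#'   or `"sd"` (points weighted by `1/sd^2` where a positive replicate
#'   s.d. is available).
#' @param audit Record every evaluated candidate parameter vector
#'   (memory-heavy; used to verify the bounds contract).
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(train_conditions = NULL,
                       transform = c("log", "linear"), bounds = NULL,
                       max_iterations = 5000, n_restarts = 3,
                       restart_jitter = 0.1, reltol = 1e-8, seed = 1L,
                       weights = c("none", "sd"), audit = FALSE) {
  transform <- match.arg(transform)
  weights <- match.arg(weights)
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      b <- bounds[[nm]]
      if (length(b) != 2 || b[1] > b[2])
        stop("bounds for ", nm, " must be c(lo, hi) with lo <= hi")
    }
  }
  structure(list(train_conditions = train_conditions,
                 transform = transform, bounds = bounds,
                 max_iterations = as.integer(max_iterations),
                 n_restarts = as.integer(n_restarts),
                 restart_jitter = restart_jitter, reltol = reltol,
                 seed = as.integer(seed), weights = weights,
                 audit = isTRUE(audit)),
            class = "fit_config")
}

grid_from_times <- function(times) {
  structure(list(t_start = times[1], t_end = times[length(times)],
                 cadence = if (length(times) > 1) times[2] - times[1]
                           else 1,
                 times = times),
            class = "time_grid")
}

#' Prepare normalized fitting data from a plate-reader dataset
#'
#' Runs the full preprocessing chain -- normalization
#' ([normalize_dataset()]), analysis-window masking
#' ([apply_analysis_window()]) and replicate aggregation
#' ([aggregate_replicates()]) -- and groups the result by condition and
#' variant.
#'
#' @param dataset A [plate_reader_dataset()].
#' @param circuit `"rna_only"` or `"hybrid"`.
#' @param od_floor Passed to [normalize_dataset()].
#' @param window Optional window override for [apply_analysis_window()].
#' @param variant_id Keep only wells of this variant (default `"base"`).
#' @return List of entries `list(condition, variant_id, timecourse)`,
#'   one per condition.
#' @export
prepare_fit_data <- function(dataset, circuit = c("rna_only", "hybrid"),
                             od_floor = 0.02, window = NULL,
                             variant_id = "base") {
  circuit <- match.arg(circuit)
  tcs <- normalize_dataset(dataset, od_floor = od_floor)
  tcs <- lapply(tcs, apply_analysis_window, circuit = circuit,
                window = window)
  keys <- vapply(tcs, function(tc)
    paste(format_condition(tc$condition), tc$meta$variant_id, sep = ";"),
    "")
  keep <- vapply(tcs, function(tc)
    identical(tc$meta$variant_id, variant_id), logical(1))
  tcs <- tcs[keep]; keys <- keys[keep]
  lapply(split(tcs, keys), function(group) {
    list(condition = group[[1]]$condition,
         variant_id = group[[1]]$meta$variant_id,
         timecourse = aggregate_replicates(unname(group)))
  })
}

#' Sum-of-squares objective against observed time courses
#'
#' For each condition, simulates the model on the observed time grid,
#' scales latent GFP by `S_G`, and accumulates the squared deviation
#' from the observed signal over unmasked points.  Conditions are
#' equally weighted.  A simulation failure at any condition contributes
#' a large penalty (1e12) instead of aborting, so the simplex search can
#' route around pathological parameter regions; the failing condition is
#' reported via a message.
#'
#' @param params Full parameter vector (`rna_only_params` /
#'   `hybrid_params`).
#' @param data List of entries `list(condition, timecourse)` with masks
#'   applied (see [prepare_fit_data()]).
#' @param model_id `"rna_only"` or `"hybrid"`.
#' @param variant Optional [circuit_variant()].
#' @param sim_options Passed to [simulate_circuit()].
#' @param weights `"none"` or `"sd"` (see [fit_config()]).
#' @return Scalar objective >= 0.
#' @export
sse_objective <- function(params, data, model_id, variant = NULL,
                          sim_options = list(), weights = "none") {
  total <- 0
  for (entry in data) {
    tc <- entry$timecourse
    if (!any(tc$mask))
      stop("all points masked for condition ",
           format_condition(entry$condition))
    sim <- tryCatch(
      simulate_circuit(model_id, params, entry$condition,
                       grid = grid_from_times(tc$times),
                       variant = variant, options = sim_options),
      error = function(e) e)
    if (inherits(sim, "error")) {
      message("simulation failed at ", format_condition(entry$condition),
              ": ", conditionMessage(sim))
      return(1e12)
    }
    pred <- params[["S_G"]] * sim$states[, gfp_state(model_id)]
    r2 <- (tc$signal - pred)[tc$mask]^2
    if (identical(weights, "sd") && !is.null(tc$sd)) {
      w <- ifelse(tc$sd[tc$mask] > 0, 1 / tc$sd[tc$mask]^2, 1)
      r2 <- r2 * w
    }
    total <- total + sum(r2)
  }
  total
}

filter_to_conditions <- function(data, conditions) {
  if (is.null(conditions)) return(data)
  want <- vapply(conditions, format_condition, "")
  keep <- vapply(data, function(e) format_condition(e$condition) %in% want,
                 logical(1))
  if (!any(keep)) stop("no data entries match the requested conditions")
  data[keep]
}

#' Fit an IFFL circuit model to normalized GFP time courses
#'
#' The package's central estimator.  Minimizes the unweighted
#' sum-of-squares deviation between the observed (normalized,
#' replicate-averaged, window-masked) GFP signal and the scaled model
#' prediction `S_G * GFP(t)`, over the free parameter set of the model
#' (see [free_parameter_names()]; the plasmid totals stay fixed), using
#' the Nelder--Mead simplex.  Unbounded fits search in log-parameter
#' space, which enforces positivity; bounded fits (required for the
#' hybrid model) search a sin^2 reparametrization of the box and never
#' evaluate outside it.  The best of `n_restarts` jittered restarts is
#' returned.
#'
#' Known degeneracy: `alpha_GFP` (or `alpha_G`) and `S_G` enter the
#' observed signal only through their product, so the objective is flat
#' along compensating rescalings; acceptance of a fit should be judged
#' on predicted trajectories, not on individual parameter values.
#'
#' @param model_id `"rna_only"` or `"hybrid"`.
#' @param data Fitting data as produced by [prepare_fit_data()].
#' @param init Full parameter vector used as the starting point (and the
#'   source of the fixed plasmid totals); must be strictly positive and,
#'   if bounds are given, inside them.
#' @param config A [fit_config()].
#' @param variant Optional [circuit_variant()].
#' @param sim_options Passed to [simulate_circuit()].
#' @return Object of class `iffl_fit` with fields `params` (full fitted
#'   vector), `objective`, `converged`, `n_evaluations`, `trace`
#'   (best objective per evaluation, non-increasing), `restart_objectives`,
#'   `seed`, `config`, `data`, `model_id`, `variant`, `eval_log` (when
#'   `config$audit`).  Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals` and `plot` methods.
#' @seealso [fit_rna_only()], [fit_hybrid()], [validate_fit()]
#' @export
iffl_fit <- function(model_id = c("rna_only", "hybrid"), data, init,
                     config = fit_config(), variant = NULL,
                     sim_options = list()) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(config, "fit_config"))
  data <- filter_to_conditions(data, config$train_conditions)
  free <- free_parameter_names(model_id)
  init <- as_iffl_params(init, model_id)
  p0 <- unclass(init)[free]

  bounds <- config$bounds
  if (!is.null(bounds)) {
    missing <- setdiff(free, names(bounds))
    if (length(missing))
      stop("bounds missing for free parameter(s): ",
           paste(missing, collapse = ", "))
    lo <- vapply(free, function(nm) bounds[[nm]][1], 0)
    hi <- vapply(free, function(nm) bounds[[nm]][2], 0)
    if (any(p0 < lo | p0 > hi))
      stop("initial parameters outside bounds: ",
           paste(free[p0 < lo | p0 > hi], collapse = ", "))
    pinned <- lo == hi
  } else {
    if (any(p0 <= 0)) stop("initial free parameters must be > 0")
    lo <- hi <- pinned <- NULL
  }

  # parameter-space encoding/decoding
  encode <- function(p) {
    if (is.null(bounds)) {
      if (config$transform == "log") log(p) else p
    } else {
      z <- rep(0, length(p))
      f <- !pinned
      z[f] <- asin(sqrt(pmin(pmax((p[f] - lo[f]) / (hi[f] - lo[f]), 0), 1)))
      z
    }
  }
  decode <- function(z) {
    if (is.null(bounds)) {
      if (config$transform == "log") exp(z) else z
    } else {
      p <- lo
      f <- !pinned
      p[f] <- lo[f] + (hi[f] - lo[f]) * sin(z[f])^2
      p
    }
  }

  env <- new.env(parent = emptyenv())
  env$n_eval <- 0L; env$trace <- numeric(0); env$best <- Inf
  env$log <- if (config$audit) list() else NULL

  full_params <- function(pfree) {
    v <- unclass(init)
    v[free] <- pfree
    as_iffl_params(v, model_id)
  }
  objfun <- function(z) {
    pfree <- stats::setNames(decode(z), free)
    val <- sse_objective(full_params(pfree), data, model_id,
                         variant = variant, sim_options = sim_options,
                         weights = config$weights)
    env$n_eval <- env$n_eval + 1L
    env$best <- min(env$best, val)
    env$trace[env$n_eval] <- env$best
    if (config$audit) env$log[[env$n_eval]] <- pfree
    val
  }

  f0 <- objfun(encode(p0))
  if (!is.finite(f0)) {
    stop("objective non-finite at the initial parameters:\n",
         paste(sprintf("  %s = %g", free, p0), collapse = "\n"))
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  best_fit <- NULL
  restart_obj <- numeric(config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    start <- if (r == 1L) p0 else {
      j <- exp(stats::runif(length(p0), log(1 - config$restart_jitter),
                            log(1 + config$restart_jitter)))
      s <- p0 * j
      if (!is.null(bounds)) s <- pmin(pmax(s, lo), hi)
      s
    }
    # a single simplex run per restart: once the data are matched to
    # within the integration noise floor the objective is flat along the
    # model's degenerate directions, and further simplex cycles would
    # only random-walk along them (see the identifiability discussion in
    # the vignette)
    res <- stats::optim(encode(start), objfun, method = "Nelder-Mead",
                        control = list(maxit = config$max_iterations,
                                       reltol = config$reltol))
    restart_obj[r] <- res$value
    if (is.null(best_fit) || res$value < best_fit$value) best_fit <- res
  }

  pf <- stats::setNames(decode(best_fit$par), free)
  structure(list(model_id = model_id,
                 params = full_params(pf),
                 free_names = free,
                 objective = best_fit$value,
                 converged = best_fit$convergence == 0,
                 n_evaluations = env$n_eval,
                 trace = env$trace,
                 restart_objectives = restart_obj,
                 seed = config$seed,
                 config = config,
                 data = data,
                 variant = variant,
                 sim_options = sim_options,
                 init = init,
                 eval_log = env$log),
            class = "iffl_fit")
}

#' Fit the RNA-only model (unconstrained log-space simplex)
#'
#' Thin wrapper around [iffl_fit()] with the RNA-only model and the
#' default unconstrained log-space Nelder--Mead search over the 15 free
#' parameters.
#'
#' @inheritParams iffl_fit
#' @return An `iffl_fit` object.
#' @export
fit_rna_only <- function(data, init, config = fit_config(),
                         variant = NULL, sim_options = list()) {
  if (!is.null(config$bounds))
    stop("fit_rna_only is unconstrained; use iffl_fit for bounded fits")
  iffl_fit("rna_only", data, init, config, variant, sim_options)
}

#' Fit the hybrid model (bound-constrained derivative-free)
#'
#' Thin wrapper around [iffl_fit()] requiring box bounds on every free
#' parameter; the search works in a sin^2 reparametrization of the box,
#' so no candidate is ever evaluated outside the bounds.
#'
#' @inheritParams iffl_fit
#' @export
fit_hybrid <- function(data, init, config, variant = NULL,
                       sim_options = list()) {
  if (is.null(config$bounds))
    stop("fit_hybrid requires bounds for every free parameter")
  iffl_fit("hybrid", data, init, config, variant, sim_options)
}

#' Validate a fit against held-out conditions
#'
#' Simulates the fitted parameters at each held-out condition and
#' reports masked RMSE and normalized RMSE (RMSE divided by the mean
#' observed signal over unmasked points).  Overlap between training and
#' held-out conditions triggers a warning (and a flag column), not an
#' error.
#'
#' @param fit An `iffl_fit`.
#' @param heldout Data entries (as from [prepare_fit_data()]) for the
#'   held-out conditions; may be empty.
#' @return Data frame with columns `condition`, `rmse`, `nrmse`, `n`,
#'   `overlaps_train`.
#' @export
validate_fit <- function(fit, heldout) {
  if (!length(heldout))
    return(data.frame(condition = character(0), rmse = numeric(0),
                      nrmse = numeric(0), n = integer(0),
                      overlaps_train = logical(0)))
  train_keys <- vapply(fit$data, function(e) format_condition(e$condition),
                       "")
  rows <- lapply(heldout, function(entry) {
    tc <- entry$timecourse
    key <- format_condition(entry$condition)
    sim <- simulate_circuit(fit$model_id, fit$params, entry$condition,
                            grid = grid_from_times(tc$times),
                            variant = fit$variant,
                            options = fit$sim_options)
    pred <- fit$params[["S_G"]] * sim$states[, gfp_state(fit$model_id)]
    res <- (tc$signal - pred)[tc$mask]
    obs <- tc$signal[tc$mask]
    data.frame(condition = key,
               rmse = sqrt(mean(res^2)),
               nrmse = sqrt(mean(res^2)) / mean(abs(obs)),
               n = sum(tc$mask),
               overlaps_train = key %in% train_keys,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$overlaps_train))
    warning("held-out set overlaps the training conditions: ",
            paste(out$condition[out$overlaps_train], collapse = ", "))
  out
}
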