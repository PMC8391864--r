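#' Sample random parameter perturbations around a nominal set
#'
#' Each draw perturbs every parameter jointly and independently, uniform
#' on the symmetric interval `[(1 - fraction) * p, (1 + fraction) * p]`
#' around its nominal value -- the "vary within +/-50%" protocol with
#' the defaults.  Plasmid totals and Hill coefficients are perturbed
#' too, unless named in `exclude`.
#'
#' @param nominal Named numeric parameter vector (e.g.
#'   [hybrid_params()]).
#' @param fraction Perturbation half-width in `[0, 1)` (default 0.5).
#' @param n_draws Number of draws (default 10).
#' @param seed RNG seed.
#' @param exclude Character vector of parameter names left at nominal.
#' @return `n_draws x length(nominal)` matrix of class
#'   `perturbation_draws` with parameters as columns.
#' @export
sample_perturbations <- function(nominal, fraction = 0.5, n_draws = 10,
                                 seed = 1L, exclude = character(0)) {
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1): larger would allow non-positive rates")
  if (n_draws < 1) stop("n_draws must be >= 1")
  nm <- names(nominal)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- matrix(stats::runif(n_draws * length(nominal), -1, 1),
              nrow = n_draws)
  draws <- sweep(1 + fraction * u, 2, unclass(nominal), `*`)
  if (length(exclude)) {
    keep <- nm %in% exclude
    draws[, keep] <- matrix(rep(nominal[keep], each = n_draws),
                            nrow = n_draws)
  }
  colnames(draws) <- nm
  structure(draws, class = c("perturbation_draws", class(draws)))
}

#' Run a parameter-perturbation ensemble across conditions
#'
#' Simulates the nominal parameter set plus `n_draws` random
#' perturbations (one full jointly-perturbed parameter vector per draw)
#' at every condition and stores the observed GFP time courses.  By
#' default the full simulation horizon stays unmasked: the analysis
#' window exists to exclude untrusted *measurement* cycles (low cell
#' density early, stationary phase late), which have no analogue in a
#' model prediction; pass `window` to impose one anyway.  A simulation
#' failure for a draw flags that draw as failed for that condition; it
#' is excluded from downstream metrics but never silently dropped.
#'
#' @param model_id `"rna_only"` or `"hybrid"`.
#' @param nominal Nominal parameter vector.
#' @param conditions List of [inducer_condition()] (defaults to the
#'   circuit's experimental grid).
#' @param fraction,n_draws,seed,exclude Passed to
#'   [sample_perturbations()].
#' @param grid [time_grid()] (default per circuit).
#' @param variant Optional [circuit_variant()].
#' @param window Optional `c(t_lo, t_hi)` analysis window to impose on
#'   the simulated time courses; default `NULL` (unmasked).
#' @param sim_options Passed to [simulate_circuit()].
#' @return Object of class `perturbation_ensemble`: fields `model_id`,
#'   `nominal`, `fraction`, `n_draws`, `seed`, `draws` (the sampled
#'   matrix), `conditions`, and `runs` -- a list per condition with the
#'   nominal time course (`nominal_tc`), the per-draw time courses
#'   (`draw_tcs`), and a logical `failed` vector.
#' @export
run_ensemble <- function(model_id = c("rna_only", "hybrid"), nominal,
                         conditions = NULL, fraction = 0.5, n_draws = 10,
                         seed = 1L, exclude = character(0), grid = NULL,
                         variant = NULL, window = NULL,
                         sim_options = list()) {
  model_id <- match.arg(model_id)
  if (is.null(conditions))
    conditions <- if (model_id == "rna_only") rna_only_conditions()
                  else hybrid_conditions()
  if (is.null(grid)) grid <- default_grid(model_id)
  draws <- sample_perturbations(nominal, fraction, n_draws, seed, exclude)

  one_tc <- function(pvec, cond) {
    params <- as_iffl_params(pvec, model_id)
    tr <- simulate_circuit(model_id, params, cond, grid = grid,
                           variant = variant, options = sim_options)
    tc <- observed_gfp(tr, params[["S_G"]])
    if (!is.null(window))
      tc <- apply_analysis_window(tc, circuit = model_id, window = window)
    tc
  }

  runs <- lapply(conditions, function(cond) {
    nom_tc <- one_tc(nominal, cond)
    failed <- logical(n_draws)
    draw_tcs <- vector("list", n_draws)
    for (k in seq_len(n_draws)) {
      res <- tryCatch(one_tc(draws[k, ], cond), error = function(e) e)
      if (inherits(res, "error")) {
        failed[k] <- TRUE
        warning(sprintf("draw %d failed at %s: %s", k,
                        format_condition(cond), conditionMessage(res)))
      } else draw_tcs[[k]] <- res
    }
    list(condition = cond, nominal_tc = nom_tc, draw_tcs = draw_tcs,
         failed = failed)
  })
  names(runs) <- vapply(conditions, format_condition, "")

  structure(list(model_id = model_id, nominal = nominal,
                 fraction = fraction, n_draws = as.integer(n_draws),
                 seed = as.integer(seed), draws = draws,
                 conditions = conditions, runs = runs,
                 variant_id = if (is.null(variant)) "base"
                              else variant$variant_id),
            class = "perturbation_ensemble")
}

#' @export
print.perturbation_ensemble <- function(x, ...) {
  nfail <- sum(vapply(x$runs, function(r) sum(r$failed), 0L))
  cat(sprintf(
    "<perturbation_ensemble> %s model: %d conditions x (nominal + %d draws), +/-%g%%\n",
    x$model_id, length(x$runs), x$n_draws, 100 * x$fraction))
  cat(sprintf("  seed %d; failed simulations: %d\n", x$seed, nfail))
  invisible(x)
}
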