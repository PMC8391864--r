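#' Serialize model and fit objects to portable formats
#'
#' Structured outputs go to JSON (model configurations, fit results,
#' ensemble manifests), tabular outputs to tidy CSV (trajectories, time
#' courses, ensembles).  Every artifact carries provenance: parameter
#' hash, seed and solver/fit settings where applicable.
#'
#' @param model_id `"rna_only"` or `"hybrid"`.
#' @param params Parameter vector.
#' @param path File path.
#' @param variant Optional [circuit_variant()].
#' @return The path, invisibly (writers); the reconstructed object
#'   (readers).
#' @name serialization
NULL

#' @rdname serialization
#' @export
write_model_config <- function(model_id, params, path, variant = NULL) {
  cfg <- list(model_id = model_id,
              params = as.list(unclass(params)),
              variant_id = if (is.null(variant)) NULL
                           else variant$variant_id,
              free_parameter_order = free_parameter_names(model_id),
              params_hash = params_hash(params))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname serialization
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- as_iffl_params(unlist(cfg$params), cfg$model_id)
  variant <- if (!is.null(cfg$variant_id)) circuit_variant(cfg$variant_id)
             else NULL
  list(model_id = cfg$model_id, params = params, variant = variant)
}

#' @param traj A `circuit_trajectory`.
#' @rdname serialization
#' @export
trajectory_to_csv <- function(traj, path) {
  long <- do.call(rbind, lapply(colnames(traj$states), function(sp)
    data.frame(time_min = traj$times, species = sp,
               value = traj$states[, sp],
               iptg_uM = traj$condition$iptg,
               arabinose_uM = traj$condition$arabinose,
               atc_nM = traj$condition$atc,
               variant = traj$variant_id,
               params_hash = traj$params_hash,
               stringsAsFactors = FALSE)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @param tc A [gfp_timecourse()].
#' @rdname serialization
#' @export
timecourse_to_csv <- function(tc, path) {
  df <- data.frame(time_min = tc$times, signal = tc$signal,
                   mask = tc$mask)
  if (!is.null(tc$sd)) df$sd <- tc$sd
  if (!is.null(tc$condition)) {
    df$iptg_uM <- tc$condition$iptg
    df$arabinose_uM <- tc$condition$arabinose
    df$atc_nM <- tc$condition$atc
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param fit An `iffl_fit`.
#' @rdname serialization
#' @export
write_fit_json <- function(fit, path) {
  out <- list(model_id = fit$model_id,
              params = as.list(unclass(fit$params)),
              free_names = fit$free_names,
              objective = fit$objective,
              converged = fit$converged,
              n_evaluations = fit$n_evaluations,
              trace = fit$trace,
              restart_objectives = fit$restart_objectives,
              seed = fit$seed,
              config = list(
                transform = fit$config$transform,
                max_iterations = fit$config$max_iterations,
                n_restarts = fit$config$n_restarts,
                restart_jitter = fit$config$restart_jitter,
                reltol = fit$config$reltol,
                weights = fit$config$weights,
                bounds = fit$config$bounds))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @param ensemble A `perturbation_ensemble`.
#' @rdname serialization
#' @export
ensemble_to_csv <- function(ensemble, path) {
  rows <- list()
  for (key in names(ensemble$runs)) {
    r <- ensemble$runs[[key]]
    add <- function(draw, tc) {
      rows[[length(rows) + 1L]] <<- data.frame(
        condition = key, draw = draw, time_min = tc$times,
        signal = tc$signal, mask = tc$mask, stringsAsFactors = FALSE)
    }
    add(0L, r$nominal_tc)
    for (k in which(!r$failed)) add(k, r$draw_tcs[[k]])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname serialization
#' @export
write_ensemble_manifest <- function(ensemble, path) {
  jsonlite::write_json(
    list(model_id = ensemble$model_id,
         fraction = ensemble$fraction,
         n_draws = ensemble$n_draws,
         seed = ensemble$seed,
         variant_id = ensemble$variant_id,
         conditions = vapply(ensemble$conditions, format_condition, ""),
         n_failed = vapply(ensemble$runs, function(r) sum(r$failed), 0L)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
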