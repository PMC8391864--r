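#' Experimental time grid
#'
#' Regular sampling grid matching the plate-reader protocol: measurements
#' every `cadence` minutes from `t_start` to `t_end`.  Defaults per
#' circuit: 0--300 min for the RNA-only circuit (31 cycles at 10-min
#' cadence, 5 h incubation) and 0--480 min for the hybrid circuit
#' (49 cycles, 8 h).
#'
#' @param t_end End time (min), > `t_start`.
#' @param t_start Start time (min), >= 0; 0 is the moment of inducer
#'   addition.
#' @param cadence Sampling interval (min), default 10.
#' @return Object of class `time_grid` with a `times` field.
#' @examples
#' length(default_grid("rna_only")$times)  # 31
#' @export
time_grid <- function(t_end, t_start = 0, cadence = 10) {
  if (t_start < 0 || t_end <= t_start || cadence <= 0)
    stop("need t_end > t_start >= 0 and cadence > 0")
  n <- floor((t_end - t_start) / cadence) + 1L
  structure(list(t_start = t_start, t_end = t_end, cadence = cadence,
                 times = t_start + cadence * (seq_len(n) - 1L)),
            class = "time_grid")
}

#' @param circuit `"rna_only"` or `"hybrid"`.
#' @rdname time_grid
#' @export
default_grid <- function(circuit = c("rna_only", "hybrid")) {
  circuit <- match.arg(circuit)
  if (circuit == "rna_only") time_grid(300) else time_grid(480)
}

# Short stable provenance token for a parameter vector (FNV-1a over the
# serialized values; no cryptographic intent).
params_hash <- function(params) {
  bytes <- as.integer(serialize(signif(unclass(params), 15), NULL))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

default_sim_options <- function() {
  list(rtol = 1e-6, atol = 1e-9, tau_T7 = 0, method = "lsoda",
       compiled = TRUE)
}

# Fold condition-constant quantities into the compiled-model parameter
# vectors (layouts documented in src/circuits.c).
compiled_parms <- function(model_id, params, cond, variant, tau) {
  if (model_id == "rna_only") {
    H <- hill_activation(cond$arabinose, params[["K_ara"]], params[["m"]])
    ip <- induced_plasmids(params, cond)
    c(params[["alpha_X"]] * params[["P_X_total"]] * H,
      params[["gamma"]], params[["omega"]],
      params[["alpha_Y"]], params[["alpha_Z"]], params[["alpha_GFP"]],
      params[["delta_X"]], params[["delta_Y"]], params[["delta_Z"]],
      params[["delta_GFP"]],
      ip[["PY_star"]], ip[["PZ_star"]],
      tau, as.numeric(is_constitutive_Y(variant)))
  } else {
    H <- hill_activation(cond$iptg, params[["K_IPTG"]], params[["n"]])
    c(params[["alpha_X"]] * params[["P_X_total"]] * H,
      params[["alpha_Y"]] * params[["P_Y_total"]],
      params[["alpha_Z"]] * H,
      params[["gamma"]], params[["omega"]],
      params[["alpha_T"]], params[["alpha_G"]],
      params[["delta_X"]], params[["delta_Y"]], params[["delta_Z"]],
      params[["delta_CY"]], params[["delta_CZ"]],
      params[["delta_T"]], params[["delta_G"]],
      params[["k_atc"]] * cond$atc, params[["k_off"]],
      params[["P_Z_total"]], tau)
  }
}

#' Simulate an IFFL circuit over an experimental time grid
#'
#' Integrates the RNA-only or hybrid model with a stiff-capable adaptive
#' solver (deSolve's `lsoda` by default) and returns the state at every
#' grid time.  Variant parameter overrides are applied internally via
#' [apply_variant()].  Small negative excursions produced by the solver
#' (within 100 x the absolute tolerance, the band the solver's
#' accumulated error can legitimately reach) are clamped to zero; larger
#' negatives raise an error rather than being silently repaired.
#'
#' @param model_id `"rna_only"` or `"hybrid"`.
#' @param params `rna_only_params` or `hybrid_params` (base values; pass
#'   `variant` for overrides).
#' @param cond [inducer_condition()].
#' @param grid [time_grid()]; defaults to the circuit's protocol grid.
#' @param init Initial state (named or unnamed, model state order);
#'   default the zero state at induction time t = 0.
#' @param variant Optional [circuit_variant()].
#' @param options List of solver options: `rtol` (default 1e-6), `atol`
#'   (default 1e-9), `tau_T7` (transcription onset delay in min, default
#'   0: the T7-driven Hill production terms are zeroed for `t < tau_T7`,
#'   representing the time needed to build up T7 RNA polymerase),
#'   `method` (any deSolve method name; `"lsoda"` default, `"rk4"` gives
#'   a fixed-step explicit reference when combined with a fine grid), and
#'   `compiled` (use the compiled right-hand sides, default `TRUE`; set
#'   `FALSE` to integrate the exported R-level [rna_only_rhs()] /
#'   [hybrid_rhs()] directly).
#' @return Object of class `circuit_trajectory`: fields `times`, `states`
#'   (samples x species matrix), `model_id`, `condition`, `variant_id`,
#'   `params_hash`.
#' @examples
#' tr <- simulate_circuit("rna_only", rna_only_params(),
#'                        inducer_condition(iptg = 500, arabinose = 6600))
#' tail(tr$states[, "GFP"], 1)
#' @export
simulate_circuit <- function(model_id = c("rna_only", "hybrid"), params,
                             cond, grid = NULL, init = NULL,
                             variant = NULL, options = list()) {
  model_id <- match.arg(model_id)
  opt <- utils::modifyList(default_sim_options(), options)
  if (is.null(grid)) grid <- default_grid(model_id)
  params <- apply_variant(params, variant)
  sn <- state_names(model_id)
  if (is.null(init)) init <- stats::setNames(numeric(length(sn)), sn)
  if (is.null(names(init))) names(init) <- sn
  if (any(init < 0)) stop("initial state must be non-negative")
  if (model_id == "hybrid" && init[["PZ_rep"]] > params[["P_Z_total"]])
    stop("initial PZ_rep exceeds P_Z_total")

  times <- grid$times
  # force a mesh point at the onset discontinuity
  tau <- opt$tau_T7
  solve_times <- if (tau > 0 && tau > times[1] && tau < times[length(times)])
    sort(unique(c(times, tau))) else times

  if (isTRUE(opt$compiled)) {
    parms <- compiled_parms(model_id, params, cond, variant, tau)
    out <- deSolve::ode(
      y = init, times = solve_times,
      func = if (model_id == "rna_only") "derivs_rna" else "derivs_hyb",
      parms = parms, dllname = "ifflpulse",
      initfunc = if (model_id == "rna_only") "initmod_rna" else "initmod_hyb",
      method = opt$method, rtol = opt$rtol, atol = opt$atol)
  } else {
    rhs <- if (model_id == "rna_only") rna_only_rhs else hybrid_rhs
    fn <- function(t, y, p) {
      # guard the strict R-side domain check against the solver's small
      # trial-step undershoots (same band as the output clamp)
      y[y < 0 & y > -100 * opt$atol] <- 0
      if (tau > 0 && t < tau) {
        # onset gating for the R path: zeroing the T7-driving inducer
        # zeroes exactly the Hill-activated production terms
        cond_off <- if (model_id == "rna_only")
          inducer_condition(iptg = cond$iptg, atc = cond$atc)
        else
          inducer_condition(arabinose = cond$arabinose, atc = cond$atc)
        return(rhs(t, y, params, cond_off, variant))
      }
      rhs(t, y, params, cond, variant)
    }
    out <- deSolve::ode(y = init, times = solve_times, func = fn,
                        parms = NULL, method = opt$method,
                        rtol = opt$rtol, atol = opt$atol)
  }

  istate <- attr(out, "istate")
  tlast <- out[nrow(out), 1]
  if (!is.null(istate) && length(istate) && !is.na(istate[1]) &&
      istate[1] < 0)
    stop(sprintf(
      "integration of %s model failed (istate %d); last good time %.3f min",
      model_id, istate[1], tlast))
  if (nrow(out) < length(solve_times))
    stop(sprintf("integration of %s model stopped early at t = %.3f min",
                 model_id, tlast))

  states <- unname(out[match(times, out[, 1]), -1, drop = FALSE])
  colnames(states) <- sn
  if (any(!is.finite(states)))
    stop("non-finite values in integrated trajectory")
  # the solver's accumulated error can exceed the per-step atol; clamp
  # within a 100 x atol guard band, treat anything larger as a failure
  neg <- states < 0
  if (any(states[neg] < -100 * opt$atol))
    stop(sprintf(
      "solver produced negative state (min %.3e) beyond tolerance",
      min(states)))
  states[neg] <- 0

  structure(list(times = times, states = states, model_id = model_id,
                 condition = cond,
                 variant_id = if (is.null(variant)) "base"
                              else variant$variant_id,
                 params_hash = params_hash(params)),
            class = "circuit_trajectory")
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf("<circuit_trajectory> %s, %s, variant %s\n", x$model_id,
              format_condition(x$condition), x$variant_id))
  cat(sprintf("  %d samples over %g-%g min; params %s\n",
              length(x$times), min(x$times), max(x$times), x$params_hash))
  invisible(x)
}

#' @export
plot.circuit_trajectory <- function(x, species = NULL, ...) {
  sp <- if (is.null(species)) colnames(x$states) else species
  graphics::matplot(x$times, x$states[, sp, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (min)", ylab = "concentration",
                    ...)
  graphics::legend("topleft", legend = sp, lty = 1,
                   col = seq_along(sp), bty = "n")
  invisible(x)
}

#' Map a latent trajectory to the observed GFP signal
#'
#' Applies the observation scale `S_G`, which converts simulated GFP
#' concentration into the blank-corrected fluorescence/OD units of the
#' normalized plate-reader signal.
#'
#' @param traj A `circuit_trajectory` containing a GFP species.
#' @param S_G Observation scale, > 0.
#' @return A [gfp_timecourse()] with all points unmasked.
#' @export
observed_gfp <- function(traj, S_G) {
  if (!is.numeric(S_G) || S_G <= 0) stop("S_G must be > 0")
  g <- gfp_state(traj$model_id)
  if (!g %in% colnames(traj$states)) stop("trajectory has no GFP species")
  gfp_timecourse(times = traj$times,
                 signal = S_G * traj$states[, g],
                 condition = traj$condition)
}

#' Observed GFP time course
#'
#' The unit of all downstream analysis: a signal on a time grid with a
#' per-point analysis-window mask.  Masked points keep their values --
#' masking controls eligibility for objectives and metrics only -- and
#' unmasking restores the original signal exactly.
#'
#' @param times Time vector (min), strictly increasing.
#' @param signal Observed GFP signal (fluorescence/OD units).
#' @param mask Logical vector, `TRUE` = point participates in analysis.
#' @param sd Optional per-point standard deviation (from replicates).
#' @param condition Optional [inducer_condition()] metadata.
#' @param meta Optional named list of extra metadata (well id, variant,
#'   replicate, flags).
#' @return Object of class `gfp_timecourse`.
#' @export
gfp_timecourse <- function(times, signal, mask = rep(TRUE, length(times)),
                           sd = NULL, condition = NULL, meta = list()) {
  if (length(times) != length(signal) || length(times) != length(mask))
    stop("times, signal and mask must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (!is.null(sd) && length(sd) != length(times))
    stop("sd must match times in length")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 mask = as.logical(mask), sd = sd,
                 condition = condition, meta = meta),
            class = "gfp_timecourse")
}

#' @export
print.gfp_timecourse <- function(x, ...) {
  cat(sprintf("<gfp_timecourse> %d points (%d unmasked), t = %g-%g min\n",
              length(x$times), sum(x$mask), min(x$times), max(x$times)))
  if (!is.null(x$condition)) cat(" ", format_condition(x$condition), "\n")
  invisible(x)
}

#' @export
plot.gfp_timecourse <- function(x, ...) {
  graphics::plot(x$times, x$signal, type = "l", xlab = "time (min)",
                 ylab = "GFP (fluorescence/OD)", ...)
  graphics::points(x$times[!x$mask], x$signal[!x$mask], col = "grey60",
                   pch = 4)
  invisible(x)
}
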