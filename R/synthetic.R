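#' Logistic cell-growth curve
#'
#' OD600 as a function of time: logistic growth from `od0` to `capacity`
#' with rate `rate`, time-shifted by `lag` and floored at `od0` before
#' the lag, emulating a culture that grows to a stationary phase.
#'
#' @param t Time (min; vectorized).
#' @param od0 Initial OD600, > 0.
#' @param rate Logistic growth rate (per min).
#' @param capacity Carrying capacity (OD units), > `od0`.
#' @param lag Lag time (min) before growth starts.
#' @return OD600 values, monotone non-decreasing in `t`.
#' @export
logistic_od <- function(t, od0, rate, capacity, lag = 0) {
  if (od0 <= 0 || capacity <= od0 || rate <= 0)
    stop("need capacity > od0 > 0 and rate > 0")
  od <- capacity / (1 + ((capacity - od0) / od0) * exp(-rate * (t - lag)))
  pmax(od, od0)
}

#' Synthetic plate-reader protocol
#'
#' Describes one emulated plate run: circuit, time grid, inducer
#' conditions, node-Y variants, replicate count, measurement noise,
#' blank level and growth parameters.  Defaults reproduce the
#' experimental protocol: 10-min cadence over 5 h (31 cycles) with 3
#' biological replicates on the 4 x 4 IPTG x arabinose grid for the
#' RNA-only circuit; 8 h (49 cycles) with 6 replicates on the 4 x 6
#' IPTG x aTc grid for the hybrid circuit.  Growth defaults reflect the
#' protocol's 1/100 (RNA-only) or 1/50 (hybrid) dilution of overnight
#' culture and a transition to stationary phase inside the run.
#'
#' @param circuit `"rna_only"` or `"hybrid"`.
#' @param grid [time_grid()]; default per circuit.
#' @param conditions List of [inducer_condition()]; default per circuit.
#' @param variants List of [circuit_variant()] or `NULL` for the base
#'   circuit only.
#' @param replicates Biological replicates per condition x variant
#'   (default 3 RNA-only, 6 hybrid).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise on fluorescence (default 0.05); OD600
#'   carries its own smaller noise (`noise_cv / 5`).
#' @param blank_level Medium autofluorescence (fluorescence units).
#' @param n_blanks Number of blank wells (default 3).
#' @param growth Named list `od0, rate, capacity, lag` for
#'   [logistic_od()].
#' @param burden Optional burden coefficient >= 0 (default 0): scales
#'   the growth rate by `1/(1 + burden * terminal latent GFP)`, a crude
#'   hook for expression load on growth.
#' @param seed Integer RNG seed; the generated dataset is a
#'   deterministic function of the protocol and this seed.
#' @return Object of class `synthetic_protocol`.
#' @export
synthetic_protocol <- function(circuit = c("rna_only", "hybrid"),
                               grid = NULL, conditions = NULL,
                               variants = NULL, replicates = NULL,
                               noise_cv = 0.05, blank_level = 100,
                               n_blanks = 3,
                               growth = NULL, burden = 0, seed = 1L) {
  circuit <- match.arg(circuit)
  if (is.null(grid)) grid <- default_grid(circuit)
  if (is.null(conditions))
    conditions <- if (circuit == "rna_only") rna_only_conditions()
                  else hybrid_conditions()
  if (is.null(replicates)) replicates <- if (circuit == "rna_only") 3L
                                         else 6L
  if (is.null(growth))
    growth <- if (circuit == "rna_only")
      list(od0 = 0.015, rate = 0.025, capacity = 0.8, lag = 20)
    else
      list(od0 = 0.03, rate = 0.02, capacity = 0.9, lag = 20)
  if (replicates < 1L) stop("replicates must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (burden < 0) stop("burden must be >= 0")
  with(growth, logistic_od(0, od0, rate, capacity, lag))  # validates
  structure(list(circuit = circuit, grid = grid, conditions = conditions,
                 variants = variants, replicates = as.integer(replicates),
                 noise_cv = noise_cv, blank_level = blank_level,
                 n_blanks = as.integer(n_blanks), growth = growth,
                 burden = burden, seed = as.integer(seed)),
            class = "synthetic_protocol")
}

# lognormal multiplicative noise with mean 1 and coefficient of
# variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic plate-reader dataset with known ground truth
#'
#' Simulates the latent GFP concentration for every condition x variant
#' of the protocol, then emits raw plate-reader observations built as
#' per-cell signal times cell density plus medium background:
#' `F(t) = blank_level + S_G * GFP(t) * OD(t) * eps(t)` with `eps`
#' lognormal (mean 1, CV `noise_cv`) independent per point, and OD600
#' reported with its own small multiplicative noise.  Blank wells
#' contain `blank_level * eps` and the protocol's growth curve.  In the
#' noiseless limit the plate-reader normalization recovers the latent
#' per-cell signal exactly: `normalize(synthesize(...)) = S_G * GFP(t)`
#' wherever OD600 is at or above the floor.
#'
#' @param model_id `"rna_only"` or `"hybrid"` (must match
#'   `protocol$circuit`).
#' @param params `rna_only_params` or `hybrid_params` (the ground truth).
#' @param protocol A [synthetic_protocol()].
#' @param sim_options Passed to [simulate_circuit()].
#' @return List with elements `dataset` (a [plate_reader_dataset()]) and
#'   `truth` (class `synthetic_ground_truth`: the parameters, the latent
#'   GFP trajectory and observed noiseless signal per condition x
#'   variant, the growth curve, the protocol and the seed -- sufficient
#'   to recompute every observation).
#' @export
synthesize_dataset <- function(model_id = c("rna_only", "hybrid"), params,
                               protocol, sim_options = list()) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(protocol, "synthetic_protocol"))
  if (protocol$circuit != model_id)
    stop("protocol circuit does not match model_id")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(protocol$seed)

  times <- protocol$grid$times
  variants <- if (is.null(protocol$variants)) list(NULL)
              else protocol$variants
  S_G <- params[["S_G"]]

  wells <- list()
  latent <- list()
  for (ci in seq_along(protocol$conditions)) {
    cond <- protocol$conditions[[ci]]
    for (vi in seq_along(variants)) {
      variant <- variants[[vi]]
      vid <- if (is.null(variant)) "base" else variant$variant_id
      traj <- simulate_circuit(model_id, params, cond,
                               grid = protocol$grid, variant = variant,
                               options = sim_options)
      gfp <- traj$states[, gfp_state(model_id)]
      g <- protocol$growth
      rate_eff <- g$rate /
        (1 + protocol$burden * gfp[length(gfp)])
      od <- logistic_od(times, g$od0, rate_eff, g$capacity, g$lag)
      key <- paste(format_condition(cond), vid, sep = ";")
      latent[[key]] <- list(condition = cond, variant_id = vid,
                            gfp = gfp, signal = S_G * gfp, od = od)
      for (rep_i in seq_len(protocol$replicates)) {
        epsF <- rlnorm_cv(length(times), protocol$noise_cv)
        epsO <- rlnorm_cv(length(times), protocol$noise_cv / 5)
        wells[[length(wells) + 1L]] <- list(
          well_id = sprintf("c%02dv%02dr%02d", ci, vi, rep_i),
          raw_fluorescence = protocol$blank_level +
            S_G * gfp * od * epsF,
          od600 = od * epsO,
          condition = cond, variant_id = vid, replicate = rep_i,
          is_blank = FALSE)
      }
    }
  }
  blank_od <- rep(0.035, length(times))  # medium-only baseline OD
  for (b in seq_len(protocol$n_blanks)) {
    epsF <- rlnorm_cv(length(times), protocol$noise_cv)
    wells[[length(wells) + 1L]] <- list(
      well_id = sprintf("blank%02d", b),
      raw_fluorescence = protocol$blank_level * epsF,
      od600 = blank_od,
      condition = inducer_condition(), variant_id = "blank",
      replicate = b, is_blank = TRUE)
  }

  truth <- structure(list(model_id = model_id, params = params,
                          latent = latent, protocol = protocol,
                          seed = protocol$seed,
                          params_hash = params_hash(params)),
                     class = "synthetic_ground_truth")
  list(dataset = plate_reader_dataset(wells, times), truth = truth)
}

# Save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
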