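#' Hill activation function
#'
#' Fractional promoter activation by an inducer at concentration `I`:
#' `I^h / (K^h + I^h)`.  Monotone non-decreasing in `I`, equal to 1/2 at
#' `I = K`, and strictly below 1 for finite `I`.
#'
#' @param I Inducer concentration, >= 0 (vectorized).
#' @param K Hill constant, > 0 (same units as `I`).
#' @param h Hill coefficient, > 0 (positive real, not restricted to
#'   integers).
#' @return Activation fraction in `[0, 1)`.
#' @examples
#' hill_activation(500, 125, 1)  # 0.8
#' @export
hill_activation <- function(I, K, h) {
  if (!is.numeric(K) || K <= 0) stop("Hill constant K must be > 0")
  if (!is.numeric(h) || h <= 0) stop("Hill coefficient h must be > 0")
  if (any(I < 0)) stop("inducer concentration must be >= 0")
  Ih <- I^h
  Ih / (K^h + Ih)
}

#' IPTG-induced plasmid pools
#'
#' The fractions of the Y and Z plasmid pools whose Lac-controlled
#' promoters are de-repressed by IPTG and hence ready for transcription
#' activation: `PY* = P_Y_total * hill(iptg; K_IPTG, n)` and analogously
#' `PZ*`.
#'
#' @param params `rna_only_params`.
#' @param cond [inducer_condition()].
#' @return Named numeric vector `c(PY_star, PZ_star)`, each in
#'   `[0, P_total]`.
#' @export
induced_plasmids <- function(params, cond) {
  H <- hill_activation(cond$iptg, params[["K_IPTG"]], params[["n"]])
  c(PY_star = unname(params[["P_Y_total"]]) * H,
    PZ_star = unname(params[["P_Z_total"]]) * H)
}

#' Right-hand side of the RNA-only IFFL model
#'
#' The four coupled ODEs of the STAR + 3WJ circuit.  X is the
#' trans-acting STAR RNA (arabinose-induced via T7 RNAP, Hill exponent
#' `m`), which activates transcription from the IPTG-induced Y and Z
#' plasmid pools (`PY*`, `PZ*`) at binding rate `gamma`; the 3WJ trigger
#' from Y neutralizes the GFP-encoding switch RNA Z at rate `omega`; GFP
#' is translated from Z.
#'
#' \deqn{dX/dt = a_X P_{X,tot} H_{ara} - \gamma X PY^* - \gamma X PZ^* - d_X X}
#' \deqn{dY/dt = a_Y \gamma X PY^* - d_Y Y - \omega Y Z}
#' \deqn{dZ/dt = a_Z \gamma X PZ^* - d_Z Z - \omega Y Z}
#' \deqn{dGFP/dt = a_{GFP} Z - d_{GFP} GFP}
#'
#' For the constitutive variant the Y production term becomes
#' `alpha_Y * PY*`, independent of X.
#'
#' The signature follows the deSolve convention, so the function can be
#' passed directly to [deSolve::ode()]; [simulate_circuit()] normally
#' uses the package's compiled equivalent.
#'
#' @param t Time (min; the system is autonomous unless an onset delay is
#'   active, see [simulate_circuit()]).
#' @param state Named state vector `c(X, Y, Z, GFP)`, all >= 0.
#' @param params `rna_only_params` with any variant overrides applied.
#' @param cond [inducer_condition()].
#' @param variant Optional `circuit_variant` (structural switches only).
#' @return `list(derivatives)` in state order (deSolve convention).
#' @export
rna_only_rhs <- function(t, state, params, cond, variant = NULL) {
  if (any(state < 0)) stop("negative state passed to rna_only_rhs")
  X <- state[["X"]]; Y <- state[["Y"]]; Z <- state[["Z"]]
  GFP <- state[["GFP"]]
  H_ara <- hill_activation(cond$arabinose, params[["K_ara"]], params[["m"]])
  ip <- induced_plasmids(params, cond)
  PYs <- ip[["PY_star"]]; PZs <- ip[["PZ_star"]]
  g <- params[["gamma"]]; w <- params[["omega"]]
  y_production <- if (is_constitutive_Y(variant))
    params[["alpha_Y"]] * PYs
  else
    params[["alpha_Y"]] * g * X * PYs
  dX <- params[["alpha_X"]] * params[["P_X_total"]] * H_ara -
    g * X * PYs - g * X * PZs - params[["delta_X"]] * X
  dY <- y_production - params[["delta_Y"]] * Y - w * Y * Z
  dZ <- params[["alpha_Z"]] * g * X * PZs - params[["delta_Z"]] * Z -
    w * Y * Z
  dGFP <- params[["alpha_GFP"]] * Z - params[["delta_GFP"]] * GFP
  list(c(X = dX, Y = dY, Z = dZ, GFP = dGFP))
}

#' Right-hand side of the RNA-protein hybrid IFFL model
#'
#' The eight coupled ODEs of the toehold-switch + TetR circuit.  The
#' trigger RNA X (IPTG-induced via T7 RNAP) binds the constitutively
#' transcribed switch RNA Y and the IPTG-induced switch RNA Z to form
#' translating complexes X:Y and X:Z (rate `gamma`, irreversible strand
#' displacement; complexes degrade first order and do not release free
#' trigger).  TetR translated from X:Y represses the free Z plasmid
#' `PZ_free = P_Z_total - PZ_rep` by operator binding at rate `omega`;
#' aTc sequesters free TetR at second-order rate `k_atc` (aTc treated as
#' a constant, non-depleting pool); `k_off` optionally relieves the
#' repressed plasmid.  GFP is translated from X:Z.
#'
#' With `H = hill(iptg; K_IPTG, n)`:
#' \deqn{dX/dt = a_X P_{X,tot} H - \gamma X Y - \gamma X Z - d_X X}
#' \deqn{dY/dt = a_Y P_{Y,tot} - \gamma X Y - d_Y Y}
#' \deqn{dZ/dt = a_Z PZ_{free} H - \gamma X Z - d_Z Z}
#' \deqn{dC_{XY}/dt = \gamma X Y - d_{CY} C_{XY}}
#' \deqn{dC_{XZ}/dt = \gamma X Z - d_{CZ} C_{XZ}}
#' \deqn{dT/dt = a_T C_{XY} - \omega T PZ_{free} - k_{atc}\,[aTc]\,T - d_T T}
#' \deqn{dPZ_{rep}/dt = \omega T PZ_{free} - k_{off} PZ_{rep}}
#' \deqn{dG/dt = a_G C_{XZ} - d_G G}
#'
#' `PZ_free` is derived, never integrated, so
#' `PZ_rep + PZ_free = P_Z_total` holds exactly.
#'
#' @param t Time (min).
#' @param state Named state vector
#'   `c(X, Y, Z, C_XY, C_XZ, T, PZ_rep, G)`, all >= 0 and
#'   `PZ_rep <= P_Z_total`.
#' @param params `hybrid_params` with any variant overrides applied.
#' @param cond [inducer_condition()].
#' @param variant Optional `circuit_variant` (hybrid variants act purely
#'   through parameter overrides; accepted for interface symmetry).
#' @return `list(derivatives)` in state order (deSolve convention).
#' @export
hybrid_rhs <- function(t, state, params, cond, variant = NULL) {
  if (any(state < 0)) stop("negative state passed to hybrid_rhs")
  # tolerate the small overshoot of an adaptive solver's trial steps;
  # a gross violation is still an error
  if (state[["PZ_rep"]] > params[["P_Z_total"]] + 1e-6)
    stop("invariant violation: PZ_rep exceeds P_Z_total")
  X <- state[["X"]]; Y <- state[["Y"]]; Z <- state[["Z"]]
  CXY <- state[["C_XY"]]; CXZ <- state[["C_XZ"]]
  T <- state[["T"]]; PZr <- state[["PZ_rep"]]; G <- state[["G"]]
  H <- hill_activation(cond$iptg, params[["K_IPTG"]], params[["n"]])
  PZ_free <- max(params[["P_Z_total"]] - PZr, 0)
  g <- params[["gamma"]]; w <- params[["omega"]]
  dX <- params[["alpha_X"]] * params[["P_X_total"]] * H -
    g * X * Y - g * X * Z - params[["delta_X"]] * X
  dY <- params[["alpha_Y"]] * params[["P_Y_total"]] -
    g * X * Y - params[["delta_Y"]] * Y
  dZ <- params[["alpha_Z"]] * PZ_free * H - g * X * Z -
    params[["delta_Z"]] * Z
  dCXY <- g * X * Y - params[["delta_CY"]] * CXY
  dCXZ <- g * X * Z - params[["delta_CZ"]] * CXZ
  dT <- params[["alpha_T"]] * CXY - w * T * PZ_free -
    params[["k_atc"]] * cond$atc * T - params[["delta_T"]] * T
  dPZr <- w * T * PZ_free - params[["k_off"]] * PZr
  dG <- params[["alpha_G"]] * CXZ - params[["delta_G"]] * G
  list(c(X = dX, Y = dY, Z = dZ, C_XY = dCXY, C_XZ = dCXZ,
         T = dT, PZ_rep = dPZr, G = dG))
}

#' Analytic steady state of the RNA-only model without Y-Z coupling
#'
#' With `omega = 0` the RNA-only system decouples and its steady state
#' has the closed form
#' `X* = alpha_X P_X_total H_ara / (delta_X + gamma PY* + gamma PZ*)`,
#' `Y* = alpha_Y gamma X* PY* / delta_Y`,
#' `Z* = alpha_Z gamma X* PZ* / delta_Z`,
#' `GFP* = alpha_GFP Z* / delta_GFP`.
#' Used as an independent oracle for the numerical integrator.
#'
#' @param params `rna_only_params` with `omega` exactly 0.
#' @param cond [inducer_condition()].
#' @return Named state vector `c(X, Y, Z, GFP)` at steady state.
#' @export
closed_form_steady_state_rna_only <- function(params, cond) {
  if (params[["omega"]] != 0)
    stop("closed-form steady state requires omega = 0 exactly")
  H_ara <- hill_activation(cond$arabinose, params[["K_ara"]], params[["m"]])
  ip <- induced_plasmids(params, cond)
  PYs <- ip[["PY_star"]]; PZs <- ip[["PZ_star"]]
  g <- params[["gamma"]]
  Xs <- params[["alpha_X"]] * params[["P_X_total"]] * H_ara /
    (params[["delta_X"]] + g * PYs + g * PZs)
  Ys <- params[["alpha_Y"]] * g * Xs * PYs / params[["delta_Y"]]
  Zs <- params[["alpha_Z"]] * g * Xs * PZs / params[["delta_Z"]]
  Gs <- params[["alpha_GFP"]] * Zs / params[["delta_GFP"]]
  c(X = unname(Xs), Y = unname(Ys), Z = unname(Zs), GFP = unname(Gs))
}
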