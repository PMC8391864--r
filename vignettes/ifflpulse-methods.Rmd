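---
title: "Modelling pulse generation in RNA-only and RNA–protein hybrid IFFL circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pulse generation in RNA-only and RNA-protein hybrid IFFL circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifflpulse)
```

## The scientific problem

A type-1 incoherent feed-forward loop (IFFL) wires an input node X to an
output node Z twice: directly as an activator, and indirectly as a
repressor through an intermediate node Y.  When the repressive arm is
slower than the activating arm, the output shows a transient pulse.
`ifflpulse` models two synthetic-biology realizations of this motif in
*E. coli* and asks when each can pulse:

* an **RNA-only circuit**, in which X is a small transcription-activating
  RNA (STAR) that switches on transcription of Y and Z, and Y produces a
  three-way-junction (3WJ) repressor RNA that silences the GFP-encoding
  switch RNA from Z.  Both arms act with fast RNA kinetics.
* an **RNA–protein hybrid circuit**, in which X is a trigger RNA that
  opens toehold switches on Y and Z; Y's switch translates the TetR
  repressor protein, which shuts down the Z promoter through its Tet
  operator.  The protein stage inserts a slow step into the repressive
  arm.

The package's central computational claim mirrors the biology: with
matched RNA kinetics the RNA-only circuit cannot produce an output
pulse over the experimentally scanned inducer grid, while the hybrid
circuit pulses robustly, even under ±50% perturbation of every kinetic
parameter.

## The kinetic models

### RNA-only circuit

States are the free species concentrations X, Y, Z and GFP (arbitrary
concentration units; time in minutes).  Inducer activation is a Hill
function \(H(I; K, h) = I^h / (K^h + I^h)\): arabinose (via T7 RNA
polymerase) activates X with constant \(K_{ara}\) and coefficient
\(m\); IPTG de-represses the Y and Z plasmid pools, giving the induced
pools \(PY^\* = P_{Y,tot}\,H(I_{IPTG}; K_{IPTG}, n)\) and analogously
\(PZ^\*\).  With binding rates \(\gamma\) (STAR activation) and
\(\omega\) (3WJ trigger–switch neutralization) and degradation rates
\(\delta\):

\[
\begin{aligned}
\dot X &= \alpha_X P_{X,tot} H_{ara} - \gamma X\,PY^\* - \gamma X\,PZ^\* - \delta_X X\\
\dot Y &= \alpha_Y \gamma X\,PY^\* - \delta_Y Y - \omega Y Z\\
\dot Z &= \alpha_Z \gamma X\,PZ^\* - \delta_Z Z - \omega Y Z\\
\dot{GFP} &= \alpha_{GFP} Z - \delta_{GFP} GFP
\end{aligned}
\]

The observed plate-reader signal is \(S_G \cdot GFP(t)\): the scale
\(S_G\) absorbs the unknown conversion between intracellular GFP
concentration and fluorescence/OD units, and is fitted jointly with the
kinetics.  The free (fittable) set is exactly the 15 parameters
returned by `free_parameter_names("rna_only")`; the plasmid totals are
fixed constants (default 1), which is what makes the free count 15.

### Hybrid circuit

The hybrid system is built from the same vocabulary plus a protein
stage.  The hybrid mechanism constrains the species and the roles of the
rates but admits more than one reaction closure; the one used here is
a minimal mass-action closure, and it is normative for everything
downstream:

* trigger–switch binding is irreversible strand displacement: X binds Y
  and Z at rate \(\gamma\), forming translating complexes
  \(C_{XY}, C_{XZ}\) that degrade first order and do not recycle free
  trigger;
* TetR is translated from \(C_{XY}\) at rate \(\alpha_T\) and binds the
  free Z-plasmid pool at rate \(\omega\), moving it into the repressed
  pool \(PZ_{rep}\) (with optional first-order relief \(k_{off}\),
  default 0); \(PZ_{free} = P_{Z,tot} - PZ_{rep}\) is derived, never
  integrated, so the plasmid pool is conserved exactly;
* aTc sequesters free TetR by a second-order reaction
  \(k_{atc}\,[aTc]\,T\) with aTc treated as a constant, non-depleting
  pool — the simplest "titration" closure;
* Y is transcribed constitutively; X and Z transcription carry the IPTG
  Hill factor.

Node-Y variants are presets over this structure
(`circuit_variant()`): the RNA-only circuit's regular / insulated (5×
effective Y production) / decoy (\(\omega = 0\)) / constitutive
(X-independent Y production) designs, and the hybrid's noTetR
(\(\alpha_T = 0\)) and ASV/AAV/LVA degradation tags, which select
increasing TetR turnover \(\delta_T\) (0.02, 0.05, 0.1 per min).

### Nominal parameter values

There is no public reference parameter set for these circuits, so the
package documents its own nominal sets
(`rna_only_params()`, `hybrid_params()`), chosen once from
field-typical scales and then verified by forward simulation to sit in
the two regimes the designs embody:

* RNA species turn over in minutes (\(\delta = 0.1\)/min, ~7 min
  half-life); the stable GFP reporter is lost mainly by growth dilution
  (\(\delta_{GFP} = 0.02\)/min).
* In the RNA-only circuit, activation and repression both act at RNA
  speed: \(\gamma = \omega = 0.05\) per concentration unit per minute.
  With matched timescales the depletion of Z by the 3WJ trigger engages
  as fast as Z accumulates, Z settles monotonically, and the slow
  reporter integrates it into a saturating, pulse-free signal.
* In the hybrid circuit the RNA-level parameters are carried over
  unchanged, and the protein stage adds the delay: TetR turnover
  \(\delta_T = 0.02\)/min sits an order of magnitude below RNA
  turnover.  Operator binding (\(\omega = 1\)) is fast relative to TetR
  turnover but slow enough that free TetR must accumulate before
  repression completes, which is what lets aTc titration
  (\(k_{atc} = 5\times10^{-4}\)/nM/min) visibly delay and enlarge the
  pulse, as observed experimentally at high aTc.

With these sets, repression of the Z pool completes within roughly
1–2 h, after which GFP decays at \(\delta_G\) — an unambiguous pulse
inside the 8 h observation window at every condition of the default
inducer grid, with enough margin that all ±50% joint perturbations
tested retain it.

## Simulation

`simulate_circuit()` integrates either model with deSolve's `lsoda`
(stiff-capable, adaptive) at `rtol = 1e-6`, `atol = 1e-9`, over the
protocol grids: 0–300 min for the RNA-only circuit and 0–480 min for
the hybrid, sampled every 10 min (31 and 49 cycles).  The right-hand
sides are compiled C for speed; the exported R implementations
(`rna_only_rhs()`, `hybrid_rhs()`) define the reference semantics and
the test suite asserts the two integrate identically.

Numerical choices worth knowing:

* **Initial condition** is the zero state at induction time t = 0
  (inducers are added to freshly diluted culture); other states can be
  supplied.
* **Negative clamping.** `lsoda` can undershoot zero by a few times the
  absolute tolerance on this system.  Values above \(-100 \cdot atol\)
  are clamped to zero; anything more negative raises an error instead
  of being silently repaired.
* **Onset delay.** An optional step delay `tau_T7` zeroes the
  T7-driven Hill production terms for \(t < \tau\), representing the
  time needed to express T7 RNA polymerase after induction (the
  mechanism suspected behind the delayed experimental pulses).  It is a
  simulation option, not a fitted parameter.
* **Oracles.** With \(\omega = 0\) the RNA-only steady state has a
  closed form (`closed_form_steady_state_rna_only()`), used to verify
  the integrator; a fixed-step 4th-order Runge–Kutta reference at
  0.01-min steps provides an independent cross-check of the adaptive
  solver on both models.

## Plate-reader normalization

`normalize_dataset()` implements the standard transformation: subtract
the per-cycle mean of the blank (medium-only) wells, divide by the
well's OD600.  The blank is time-varying because medium
autofluorescence drifts.  Cycles with OD600 below `od_floor`
(default 0.02) are masked, not dropped — masking controls eligibility
for objectives and metrics and never alters stored values.
`apply_analysis_window()` adds the protocol windows: 90–200 min for the
RNA-only circuit and 50–300 min for the hybrid (early points have
unreliably low OD; late points sit in stationary phase where the
GFP/OD proxy breaks down).  On the default grids that leaves 12 and 26
analysable cycles respectively.

## Synthetic data generation

`synthesize_dataset()` emulates the plate protocol end to end with
known ground truth.  Raw fluorescence is modelled as per-cell signal
times cell density plus medium background:
\(F(t) = blank + S_G\,GFP(t)\,OD(t)\,\varepsilon(t)\), with
multiplicative lognormal noise (mean 1, CV `noise_cv`, default 0.05 —
typical plate-reader signal-proportional error), OD600 reported with
its own smaller noise (CV/5), and logistic growth with lag and
stationary phase.  This observation model is chosen so that the
normalization recovers the latent per-cell signal *exactly* in the
noiseless limit, which turns the correctness of the normalization step
into a testable identity rather than an approximation.

Defaults mirror the experimental protocol: 3 biological replicates on
the 4 × 4 IPTG × arabinose grid for the RNA-only circuit (IPTG 500,
125, 31.2, 7.81 µM; arabinose 6600, 1650, 412.5, 103.1 µM), 6
replicates on the 4 × 6 IPTG × aTc grid for the hybrid (IPTG 1, 0.2,
0.1, 0.02 mM; aTc 400, 200, 40, 20, 4, 2 nM).  The aTc series is dosed in ng/mL (200, 100, 20, 10, 2, 1); the nM
list includes the 20 nM level corresponding to the 20 ng/mL dose.  Growth parameters are
condition-independent by default (an optional `burden` hook scales the
growth rate with terminal expression).  What the generator does *not*
emulate: expression–growth coupling, well-position and evaporation
effects, saturation of promoter activity at high inducer doses, and
the non-monotone inducer responses seen in real data.  Tests passing on
synthetic data therefore validate the pipeline's internal consistency,
not the biological fidelity of the model.

## Parameter fitting and identifiability

`iffl_fit()` (wrapped by `fit_rna_only()` / `fit_hybrid()`) minimizes
the unweighted sum of squared deviations between the replicate-mean
normalized signal and \(S_G\,GFP(t)\), over unmasked points, conditions
equally weighted.  The optimizer is the Nelder–Mead simplex: in log
parameter space for the RNA-only model (positivity by construction,
the classic unconstrained simplex setup), and in a
\(\sin^2\) reparametrization of a required box for the hybrid model, so
that no candidate is ever evaluated outside its bounds.  Defaults: 3
restarts with 10% log-space jitter, objective relative tolerance 1e-8,
5000 iterations per restart, one simplex run per restart.  A
simulation failure inside the objective contributes a 1e12 penalty so
the simplex can route around pathological regions.  The default
training split is the original one: IPTG {500, 7.81} µM crossed with
arabinose {6600, 1650, 103.1} µM; the other ten grid conditions form
the validation set.

Two exact degeneracies of this design are worth documenting rather
than hiding:

* **Scale degeneracy.** \(\alpha_{GFP}\) (or \(\alpha_G\)) and
  \(S_G\) enter the observed signal only through their product;
  compensating rescalings leave the objective exactly flat.  Fits are
  therefore judged on predicted trajectories, never on individual
  parameter values.
* **Two-point Hill degeneracy.** The training split contains only two
  IPTG levels.  A Hill curve has two shape parameters
  \((K_{IPTG}, n)\), so a one-parameter family of curves reproduces
  any common rescaling of the two training activations, and a
  compensating \(\gamma\) rescale then leaves *all* training
  trajectories exactly unchanged.  Training data alone consequently
  cannot pin the interior of the IPTG dose–response: deviations appear
  only at the validation IPTG levels (125 and 31.2 µM).  Because the
  training objective is exactly flat along this family, prolonged
  simplex iteration performs a random walk along it; the default of a
  single simplex run per restart deliberately avoids that regime, and
  recovery experiments show validation-trajectory errors at the
  percent level from a ±10% jittered start.  Users who need the IPTG
  response pinned should add an interior IPTG level to the training
  split.

`validate_fit()` reports masked RMSE and normalized RMSE per held-out
condition, warning (not failing) on train/validation overlap.

## Sensitivity analysis

`sample_perturbations()` draws each parameter independently and
uniformly on \([(1-f)p, (1+f)p]\) — the symmetric additive-fraction
reading of "±50%" — with every free parameter perturbed jointly per
draw, ten draws per condition by default.  `run_ensemble()` simulates
nominal plus draws at every condition of the experimental grid.
Simulated ensemble trajectories are left unmasked by default: the
analysis window exists to excise untrusted measurement cycles, which
have no analogue in model predictions; a window can be imposed when
ensembles are compared against measured data.

## Pulse detection

Visual inspection identifies pulses qualitatively; automated analysis
needs a decision rule, so the package defines one (`detect_pulse()`): over the
unmasked window, the maximum must be strictly interior, the signal
must rise by at least 20% of the peak from the window start and fall
by at least 20% of the peak by the window end.  Ties at the peak break
to the earliest time; an all-zero signal is "no pulse" with both
fractions reported as 0.  The rule is scale-invariant, and raising
either threshold is monotone (it can only turn pulses off).  The
thresholds are exposed because they are a convention, not an estimate.
`pulse_fraction()` aggregates the rule over an ensemble, reporting
conditions whose draws all failed as missing rather than 0.

## Problem sizes and runtime

The test and acceptance workloads are sized for a single CPU: the
steady-state oracle uses 100 random ±50% draws; the integrator
cross-check compares both models against a 0.01-min fixed-step
reference; the recovery experiment fits 15 parameters to 6 noiseless
training conditions (3 restarts); the dichotomy check simulates
nominal + 10 draws at all 16 RNA-only and 24 hybrid conditions
(440 trajectories).  End to end this stays within a few minutes.

## Known limitations

* The hybrid reaction closure is one of several defensible choices; plausible
  alternative closures (complex dissociation, trigger recycling,
  catalytic aTc-mediated release of operator-bound TetR) would change parameter
  meanings, though not the timescale-separation argument.
* Whether a hybrid circuit realized in vivo shares the RNA-only
  \(\gamma\) exactly is an open experimental question; the nominal
  sets assume it does, and `fit_hybrid()` exposes re-fitting with bounds centred on
  RNA-only values as the corresponding workflow.
* Deterministic ODEs only: no stochastic (SSA) simulation, no
  multi-copy plasmid replication dynamics, no resource competition.
* Growth and expression are uncoupled by default; stationary-phase
  physiology is handled by masking, not mechanism.
* Inducers are constant after t = 0; the only time-dependence offered
  is the step onset delay `tau_T7`.
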