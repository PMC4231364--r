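---
title: "Models and methods behind hydrokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hydrokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrokin)
```

hydrokin analyzes the kinetics and stability of polyester-degrading
hydrolases — cutinase-like serine hydrolases that erode insoluble polymer
substrates such as poly(ε-caprolactone) (PCL) and polyethylene
terephthalate (PET). This vignette explains the models the package fits,
the assumptions behind its synthetic-data generators, and the numerical
choices a user should know about.

## The turbidimetric erosion model

Polyester nanoparticle suspensions scatter light; as enzymes erode the
particles, absorbance at 600 nm (turbidity, τ) falls. Unlike
homogeneous catalysis, the reaction happens on a surface: the enzyme must
first adsorb, and the observed rate saturates as the surface fills. The
kinetic model is a Langmuir-type adsorption saturation,

$$ R(E) \;=\; \frac{k_\tau \, K_A \, [E]}{1 + K_A\,[E]}, $$

where $[E]$ is the enzyme concentration (mg/mL), $K_A$ (mL/mg) the
adsorption equilibrium constant, and $k_\tau$ (min⁻¹) the saturating rate
constant. Half saturation occurs at $[E] = 1/K_A$, so a larger $K_A$
means stronger apparent substrate affinity. Note that $K_A[E]$ is
dimensionless, which is why the package canonicalizes enzyme
concentrations to mg/mL at I/O boundaries (µg/mL inputs are converted,
never silently reinterpreted).

**Rate observable.** The fitted rate is defined as
$-\,d\sqrt{\tau/\tau_0}/dt$, the initial decrease rate of the
*square-root* normalized turbidity, and $k_\tau$ carries the same unit.
The square root comes from a shrinking-particle argument: for particles
of radius $r$ at constant number density, geometric scattering gives
$\tau \propto N r^2$, and constant surface erosion shrinks $r$ linearly
in time — so $\sqrt{\tau/\tau_0}$ is affine in $t$ during the initial
phase. The model is deliberately minimal: polydispersity, Mie scattering
corrections and particle break-up are excluded, which is why only the
*initial* linear phase is used for rate estimation.

**Initial-rate windows.** Two policies are provided. `window_fixed()`
(default) uses the full sampled trace, matching assay protocols that only
record the initial phase (15 min at 1-min intervals for PCL in
microplates; 60 min at 5-min intervals for PET immobilized in agarose).
`window_auto()` instead grows the longest prefix of at least 4 samples
whose ordinary-least-squares fit keeps $R^2 \ge 0.98$; use it whenever a
trace may run into substrate depletion, where $\sqrt{\tau/\tau_0}$
flattens at zero and would bias a full-trace slope.

**Supra-maximal exclusion.** At enzyme loads beyond the empirical rate
maximum, real assays can show *decreasing* rates — excess enzyme adsorbs
beyond monolayer coverage without contributing catalysis. The saturation
model is monotone and cannot represent this, so `fit_saturation()` by
default excludes points whose concentration lies strictly beyond the last
maximal observed rate, logs them in `excluded_points`, and lets you
disable the rule (`exclude_supramaximal = FALSE`). On monotone noisy data
the rule occasionally clips the top concentration and nudges the fitted
$K_A$ slightly downward (about 1–2% in the median at 3% assay noise);
this is the price of robustness against genuinely inhibited points and is
visible in the package's own recovery studies.

**Fitting.** Starting values come from the double-reciprocal
linearization $1/R = 1/k_\tau + 1/(k_\tau K_A E)$ fitted by OLS on the
positive rates (exact on noise-free data); Levenberg–Marquardt refinement
(via minpack.lm) then minimizes the untransformed residuals to a relative
parameter tolerance of 1e-10, so the reciprocal transform's noise
distortion never reaches the final estimates. If the linearization is
degenerate (non-positive rates), the fallback start is
$k_\tau^0 = 1.5\max(R)$, $K_A^0 = 1/\mathrm{median}(E)$. Standard errors
and the parameter covariance use the Gauss–Newton approximation at the
optimum and are reported as 1 SE. Weighting is unweighted by default;
`weighting = "inverse_se2"` activates $1/\mathrm{SE}^2$ weights when
replicate-based errors are available.

```{r saturation-example}
sc <- erosion_scenario(k_tau = 4.1e-3, K_A = 44.4,
                       enzyme_concs = seq(0.005, 0.08, length.out = 8),
                       duration = 60, dt = 5)
fit_saturation(simulate_rate_dataset(sc, substrate = "PET", temperature = 50))
```

## Soluble-substrate and stability assays

**Michaelis–Menten.** For chromogenic soluble esters (p-nitrophenyl
butyrate, pNPB), `fit_michaelis_menten()` fits
$v = V_{max} S/(K_m + S)$ with a Lineweaver–Burk initializer and the same
Levenberg–Marquardt refinement; $k_{cat} = V_{max}/E_0$ is derived when
the enzyme concentration is supplied. A scaled-Jacobian condition number
above 1e6 flags grids that do not bracket $K_m$ (all-saturating or
all-linear designs) in `identifiability_warning` rather than failing:
the point estimate may still be useful, but its covariance is not.
One enzyme unit (U) is 1 µmol pNPB hydrolyzed per minute; conversions
between U/mg and $k_{cat}$ require a molar mass and are never performed
implicitly.

**Thermal inactivation.** Residual-activity time courses are modeled as
single-exponential first-order decay $A(t) = e^{-k_d t}$ with
$t_{1/2} = \ln 2/k_d$. The single-exponential form is the minimal model
for irreversible denaturation and is a deliberate choice — published
stability curves for these enzymes are shown graphically, not numerically,
so nothing richer (biphasic decay, aggregation terms) is identifiable.
The fit is initialized by intercept-free least squares on $\log A$
(the model forces $A(0)=1$) and refined on the original scale, which
keeps the heavier weighting of early, well-measured points.

**pH/temperature profiles.** `profile_summary()` is purely descriptive:
activities are normalized to their maximum, the optimum is the grid
argmax, and `fraction_at()` interpolates linearly. No smoothing is
applied, so the optimum is only resolved to the grid spacing.

## Trajectory stability metrics

Thermal unfolding seen in molecular-dynamics simulations is summarized by
three operators, implemented from first principles on a
frames × atoms × 3 coordinate array:

* `kabsch_superpose()` — optimal rigid-body alignment via SVD of the 3×3
  cross-covariance, with the sign of the smallest singular direction
  corrected so the rotation is proper (det = +1, orthogonal to 1e-8);
  collinear selections are rejected as ill-posed.
* `rmsd_timeseries()` — per-frame superposition on a selection
  (`"backbone"` = atoms named N, CA, C, O) followed by RMSD over that
  selection, in Å with an nm option for figure parity.
* `rmsf_per_residue()` — per-atom fluctuation about the time-averaged
  position after removing global motion by a two-pass superposition
  (align to the first frame, recompute the mean, align to the mean).
  For isotropic per-coordinate noise of s.d. σ the expected RMSF is
  σ√3. Beware a small-system effect: superposition absorbs 6 of the 3N
  coordinate degrees of freedom, shrinking the measured RMSF by
  ≈ √(1 − 6/3N) — negligible for proteins, visible on toy systems.
* `distance_timeseries()` — Euclidean distance between two uniquely
  selected atoms; the canonical use is the catalytic His–Ser distance
  (His Nε2 to Ser Oγ by default, the hydrogen-bond geometry of the
  Ser-His-Asp triad), whose drift signals active-site disruption before
  global unfolding.

Selections use `"chain:resno:atomname"` patterns with `*` wildcards or
the keywords `backbone`/`calpha`. Multi-model PDB I/O keeps the fixed
8.3-column precision (round trips are exact to 1e-3 Å), retains altloc
'A'-or-blank atoms, and preserves insertion codes in residue keys.

## Synthetic-data generators

Every analysis stage is testable without external data because the
package ships forward simulators with the statistical structure the
analysis assumes:

* `simulate_turbidity_curves()` emits
  $\tau(t) = \tau_0\max(0,\,1 - R(E)t)^2$ — affine $\sqrt{\tau/\tau_0}$
  until depletion, clamped at zero once the suspension is fully
  hydrolyzed — with *multiplicative* Gaussian noise (plate-reader
  behavior: error scales with signal). Defaults are the PCL microplate
  protocol (15 min at 1-min steps, τ₀ = 0.5 absorbance units, a typical
  A600 for 0.22–0.25 mg/mL nanoparticle suspensions).
* `simulate_rate_dataset()` shortcuts to $(E, R(E))$ pairs for
  Monte-Carlo studies of the fit itself.
* An optional crowding term multiplies $R(E)$ by the smooth Hill-type
  factor $1/(1 + (E/E_{inh})^h)$, default off, to emulate the
  supra-maximal rate decline; it is applied over the whole concentration
  range rather than switched on at the threshold, avoiding a
  discontinuity the data could not support.
* `simulate_mm_dataset()` and `simulate_decay_dataset()` add
  multiplicative noise to velocities and *additive* noise to activity
  fractions (absorbance-ratio measurements have roughly constant absolute
  error), clipping fractions to [0, 1.05].
* `simulate_trajectory()` perturbs a reference structure with per-atom
  Gaussian displacements and optional random rigid motion per frame —
  exactly the component superposition must remove.

Seeds are mandatory arguments (default 1); generators restore the
caller's RNG state, and identical seeds give bit-identical output. What
the simulators do *not* emulate: correlated residuals, instrument drift,
particle polydispersity, non-exponential inactivation, and anharmonic
protein dynamics. Passing recovery tests therefore demonstrates the
estimators are correct and well-conditioned under the assumed noise
model, not that the models are adequate for any particular real assay.

## Pipeline and reproducibility

`run_pipeline()` ties CSV input (or in-memory curves) through rate
estimation and per-condition saturation fits into a serializable report;
conditions fail independently, window and exclusion decisions are logged
at INFO, and the JSON report contains a config hash, the seed and the
package version but no timestamps, so identical runs are byte-identical.
The problem sizes used in the package's own recovery studies — 200
replicates for stochastic parameter-recovery medians, 10⁴ frames for
fluctuation recovery, 500 replicates for decay recovery — were chosen so
each Monte-Carlo standard error sits well inside the tolerance being
checked.

## Known limitations

* The turbidity–radius link assumes geometric scattering at constant
  particle number; strongly polydisperse or aggregating suspensions
  violate it.
* $K_A$ is only identifiable when the concentration grid brackets
  $1/K_A$; grids entirely in the saturated regime leave it poorly
  determined (large SEs, honest covariance).
* The supra-maximal exclusion rule is a heuristic; with very noisy
  monotone data it can clip informative points (disable it when the
  crowding effect is known to be absent).
* Whether published "±" uncertainties of this assay family are fit SEs
  or duplicate SDs is generally unstated; the package reports 1 SE of
  the fit and leaves cross-study comparison to the user.
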