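# hydrokin

Kinetic and structural-stability analysis of polyester-degrading
hydrolases.

Cutinase-like serine hydrolases from thermophilic actinomycetes can
hydrolyze synthetic polyesters such as poly(ε-caprolactone) (PCL) and
polyethylene terephthalate (PET). Characterizing them quantitatively
requires a chain of small but easy-to-get-wrong analyses, because the
substrate is an insoluble particle suspension rather than a dissolved
compound. hydrokin implements that chain for R users — enzymologists and
biodegradation researchers working with turbidimetric nanoparticle
assays, chromogenic esterase assays, and molecular-dynamics output.

## What it computes

**Turbidimetric erosion kinetics.** The degradation of a nanoparticle
suspension is followed as turbidity τ at 600 nm. Under a
shrinking-particle model, √(τ/τ₀) falls linearly during the initial
phase, and its initial rate saturates in enzyme concentration through an
adsorption equilibrium:

    R(E) = k_tau * K_A * [E] / (1 + K_A * [E])

with `k_tau` (min⁻¹) the saturating rate constant and `K_A` (mL/mg) the
adsorption equilibrium constant (half-saturation at `[E] = 1/K_A`).
`estimate_initial_rate()` turns traces into rates (fixed or automatic
linear-phase windows), `fit_saturation()` fits the model
(double-reciprocal initializer, Levenberg–Marquardt refinement,
supra-maximal point exclusion), and `fold_change()` compares enzymes.

**Soluble-substrate and stability assays.** Michaelis–Menten fits for
p-nitrophenyl butyrate data (`fit_michaelis_menten()`, with
`k_cat = V_max/E0`), first-order thermal inactivation with half-lives
(`fit_decay()`), and descriptive pH/temperature activity profiles
(`profile_summary()`).

**Trajectory stability metrics.** From-scratch Kabsch superposition,
backbone RMSD time courses, per-residue Cα RMSF, and catalytic-pair
(His–Ser) distance series, with multi-model PDB and XYZ I/O and a
`chain:resno:atomname` selection language.

**Synthetic data.** Seeded forward simulators for every input —
turbidity curves, rate and velocity datasets, residual-activity tables,
rigid-body-perturbed trajectories — so the whole pipeline is testable
without any external data.

## Worked example

Simulate a PET assay at 50°C for an enzyme with `k_tau = 4.1e-3` min⁻¹
and `K_A = 44.4` mL/mg, 2% plate-reader noise, and recover the constants:

```r
library(hydrokin)

sc <- erosion_scenario(k_tau = 4.1e-3, K_A = 44.4,
                       enzyme_concs = seq(0.005, 0.08, length.out = 8),
                       duration = 60, dt = 5, noise_rel = 0.02, seed = 1)
curves <- simulate_turbidity_curves(sc, substrate = "PET",
                                    temperature = 50, enzyme = "Tcur1278")
report <- run_pipeline(run_config(curves, seed = 1, log_level = "ERROR"))
print(report$fits[[1]])
#> Adsorption-saturation fit: R(E) = k_tau * K_A * E / (1 + K_A * E)
#>   k_tau = 0.00444 +/- 0.00019 1/min
#>   K_A   = 36.57 +/- 4.1 mL/mg
#>   R^2 = 0.9914 on 8 points (0 excluded as supra-maximal)
```

The recovered `k_tau` (0.00444 ± 0.00019 min⁻¹) and `K_A`
(37 ± 4 mL/mg) bracket the generating truth within roughly one to two
standard errors — exactly what one noisy 8-point assay can resolve; at
`noise_rel = 0` the fit returns the generating values to 1e-6 relative.
The same objects come from CSV input via `read_turbidity_csv()` plus a
`condition_map()`, or from the shell via the thin CLI
(`inst/exec/hydrokin`, subcommands `simulate-turbidity`, `rates`,
`fit-saturation`, `run`, ...).

Soluble-substrate kinetics, noise-free:

```r
d <- simulate_mm_dataset(mm_scenario(K_m = 88.8, k_cat = 2.3, E0 = 0.1,
                                     substrate_concs = 10^seq(1, 3, length.out = 10)))
fit_michaelis_menten(d$S, d$v, E0 = 0.1)
#> Michaelis-Menten fit: v = V_max * S / (K_m + S)
#>   K_m   = 88.8 +/- 2.4e-14 uM
#>   V_max = 0.23 +/- 1.9e-17 uM/s
#>   k_cat = 2.3 +/- 1.9e-16 1/s (E0 = 0.1 uM)
#>   R^2 = 1.0000
```

Thermal stability, anchored at 40% residual activity after 60 min:

```r
t <- seq(0, 60, by = 10)
fit_decay(t, exp(-log(2.5) / 60 * t))
#> First-order inactivation fit: A(t) = exp(-k_d t)
#>   k_d = 0.01527 +/- 0 1/min; t1/2 = 45.39 min; R^2 = 1.0000
```

See `vignettes/hydrokin-methods.Rmd` for the models, assumptions and
numerical choices in detail.

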