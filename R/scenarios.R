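#' Scenario for simulating turbidimetric polyester-erosion assays
#'
#' Bundles the parameters of the adsorption-saturation erosion model and the
#' assay protocol into a validated object consumed by
#' [simulate_turbidity_curves()] and [simulate_rate_dataset()]. The model is
#' \deqn{R(E) = k_\tau K_A E / (1 + K_A E)}
#' where `R(E)` is the initial decrease rate of \eqn{\sqrt{\tau/\tau_0}}
#' (per minute), `k_tau` its saturating value and `K_A` (mL/mg) the
#' adsorption equilibrium constant: half saturation occurs at `E = 1/K_A`.
#'
#' Defaults mirror a microplate poly(caprolactone) nanoparticle assay:
#' 15 min sampled at 1-min intervals, initial absorbance 0.5 at 600 nm.
#'
#' @param k_tau Saturating sqrt-turbidity rate constant (1/min), > 0.
#' @param K_A Adsorption equilibrium constant (mL/mg), > 0.
#' @param enzyme_concs Enzyme concentrations (mg/mL), >= 0.
#' @param tau0 Initial turbidity (absorbance units at 600 nm), > 0.
#' @param duration Assay length (min), at least `2 * dt`.
#' @param dt Sampling interval (min), > 0.
#' @param noise_rel Relative (multiplicative) Gaussian noise s.d., >= 0.
#' @param seed Integer RNG seed (mandatory for reproducibility; default 1).
#' @param crowding Optional list `list(threshold =, hill =)` enabling a
#'   smooth high-concentration inhibition factor
#'   \eqn{1/(1+(E/\mathrm{threshold})^{\mathrm{hill}})} that emulates the
#'   rate decline seen when excess inactive enzyme crowds the particle
#'   surface. `NULL` (default) disables it.
#' @param n_replicates Replicate curves per concentration.
#' @return An object of class `erosion_scenario`.
#' @seealso [simulate_turbidity_curves()], [fit_saturation()]
#' @export
erosion_scenario <- function(k_tau, K_A, enzyme_concs,
                             tau0 = 0.5, duration = 15, dt = 1,
                             noise_rel = 0, seed = 1,
                             crowding = NULL, n_replicates = 1L) {
  check_scalar(k_tau, "k_tau", positive = TRUE)
  check_scalar(K_A, "K_A", positive = TRUE)
  check_numeric_vec(enzyme_concs, "enzyme_concs", nonneg = TRUE)
  check_scalar(tau0, "tau0", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  if (duration < 2 * dt)
    hk_stop_invalid("duration", "must be at least 2 * dt")
  check_scalar(noise_rel, "noise_rel", nonneg = TRUE)
  check_scalar(seed, "seed")
  if (!is.null(crowding)) {
    if (!is.list(crowding) || is.null(crowding$threshold))
      hk_stop_invalid("crowding", "must be NULL or list(threshold =, hill =)")
    check_scalar(crowding$threshold, "crowding$threshold", positive = TRUE)
    crowding$hill <- crowding$hill %||% 2
    check_scalar(crowding$hill, "crowding$hill", positive = TRUE)
  }
  check_scalar(n_replicates, "n_replicates", positive = TRUE)
  structure(list(
    k_tau = k_tau, K_A = K_A, enzyme_concs = enzyme_concs, tau0 = tau0,
    duration = duration, dt = dt, noise_rel = noise_rel,
    seed = as.integer(seed), crowding = crowding,
    n_replicates = as.integer(n_replicates)
  ), class = "erosion_scenario")
}

#' Scenario for simulating Michaelis-Menten velocity data
#'
#' @param K_m Michaelis constant (µM), > 0.
#' @param k_cat Turnover number (1/s), > 0.
#' @param E0 Enzyme concentration (µM), > 0.
#' @param substrate_concs Substrate concentrations (µM), strictly positive.
#' @param noise_rel Relative Gaussian noise s.d. on velocities, >= 0.
#' @param seed Integer RNG seed.
#' @return An object of class `mm_scenario`.
#' @export
mm_scenario <- function(K_m, k_cat, E0, substrate_concs,
                        noise_rel = 0, seed = 1) {
  check_scalar(K_m, "K_m", positive = TRUE)
  check_scalar(k_cat, "k_cat", positive = TRUE)
  check_scalar(E0, "E0", positive = TRUE)
  check_numeric_vec(substrate_concs, "substrate_concs", positive = TRUE)
  check_scalar(noise_rel, "noise_rel", nonneg = TRUE)
  check_scalar(seed, "seed")
  structure(list(K_m = K_m, k_cat = k_cat, E0 = E0,
                 substrate_concs = substrate_concs,
                 noise_rel = noise_rel, seed = as.integer(seed)),
            class = "mm_scenario")
}

#' Scenario for simulating first-order thermal-inactivation data
#'
#' Emulates a residual-activity protocol: an enzyme stock is held at an
#' elevated temperature and aliquots are assayed at 25°C, giving the
#' remaining fraction of initial activity at each hold time.
#'
#' @param k_d First-order inactivation rate constant (1/min), >= 0.
#' @param times Sampling times (min), non-negative and increasing.
#' @param noise_abs Additive noise s.d. on the activity fraction.
#' @param seed Integer RNG seed.
#' @return An object of class `decay_scenario`.
#' @export
decay_scenario <- function(k_d, times, noise_abs = 0, seed = 1) {
  check_scalar(k_d, "k_d", nonneg = TRUE)
  check_numeric_vec(times, "times", nonneg = TRUE)
  if (is.unsorted(times, strictly = TRUE))
    hk_stop_invalid("times", "must be strictly increasing")
  check_scalar(noise_abs, "noise_abs", nonneg = TRUE)
  check_scalar(seed, "seed")
  structure(list(k_d = k_d, times = times, noise_abs = noise_abs,
                 seed = as.integer(seed)),
            class = "decay_scenario")
}

#' Scenario for simulating rigid-body-perturbed atomic trajectories
#'
#' Frames are built as `ref + per-atom Gaussian displacement`, optionally
#' followed by a random global rotation and translation per frame, which is
#' what superposition-based metrics (RMSD/RMSF) must remove.
#'
#' @param n_atoms Number of atoms (>= 3 when `rigid_motion` is on, so that
#'   superposition is well-posed).
#' @param n_frames Number of frames.
#' @param reference_coords `n_atoms x 3` matrix of reference positions (Å);
#'   default: points on a loose helix, which is never collinear.
#' @param per_atom_sigma Per-coordinate fluctuation s.d. per atom (Å);
#'   scalar or length `n_atoms`, >= 0.
#' @param rigid_motion Apply a random rotation + translation per frame?
#' @param dt_ns Frame spacing (ns) used for the attached frame times.
#' @param seed Integer RNG seed.
#' @return An object of class `trajectory_scenario`.
#' @export
trajectory_scenario <- function(n_atoms, n_frames, reference_coords = NULL,
                                per_atom_sigma = 0.5, rigid_motion = TRUE,
                                dt_ns = 0.01, seed = 1) {
  check_scalar(n_atoms, "n_atoms", positive = TRUE)
  n_atoms <- as.integer(n_atoms)
  check_scalar(n_frames, "n_frames", positive = TRUE)
  if (rigid_motion && n_atoms < 3L)
    hk_stop_invalid("n_atoms", "must be >= 3 when rigid_motion is enabled")
  if (is.null(reference_coords)) {
    i <- seq_len(n_atoms)
    reference_coords <- cbind(3 * cos(i / 2), 3 * sin(i / 2), 1.5 * i)
  }
  reference_coords <- as.matrix(reference_coords)
  if (nrow(reference_coords) != n_atoms || ncol(reference_coords) != 3 ||
      anyNA(reference_coords) || !all(is.finite(reference_coords)))
    hk_stop_invalid("reference_coords", "must be a finite n_atoms x 3 matrix")
  if (length(per_atom_sigma) == 1L)
    per_atom_sigma <- rep(per_atom_sigma, n_atoms)
  check_numeric_vec(per_atom_sigma, "per_atom_sigma", nonneg = TRUE,
                    min_len = n_atoms)
  if (length(per_atom_sigma) != n_atoms)
    hk_stop_invalid("per_atom_sigma", "must have one value per atom")
  check_scalar(dt_ns, "dt_ns", positive = TRUE)
  check_scalar(seed, "seed")
  structure(list(n_atoms = n_atoms, n_frames = as.integer(n_frames),
                 reference_coords = reference_coords,
                 per_atom_sigma = per_atom_sigma,
                 rigid_motion = isTRUE(rigid_motion),
                 dt_ns = dt_ns, seed = as.integer(seed)),
            class = "trajectory_scenario")
}
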