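# Forward simulators. Every generator is deterministic given its scenario
# seed and leaves the caller's RNG state untouched.

crowding_factor <- function(E, crowding) {
  if (is.null(crowding)) return(rep(1, length(E)))
  1 / (1 + (E / crowding$threshold)^crowding$hill)
}

erosion_rate <- function(scenario, E) {
  predict_rate(scenario$k_tau, scenario$K_A, E) * crowding_factor(E, scenario$crowding)
}

#' Simulate turbidity decay curves for a panel of enzyme concentrations
#'
#' For each enzyme concentration `E` and replicate, the noise-free turbidity
#' follows a shrinking-particle model: under constant surface erosion the
#' particle radius decreases linearly in time, and with turbidity
#' proportional to the particle cross-section (\eqn{\tau \propto N r^2} at
#' constant particle number) the square root of the normalized turbidity is
#' affine in time until depletion,
#' \deqn{\tau(t) = \tau_0 \max(0,\; 1 - R(E)\,t)^2,}
#' with \eqn{R(E) = k_\tau K_A E/(1+K_A E)}. Multiplicative Gaussian noise
#' (plate-reader behavior) is then applied and values are clamped at zero.
#'
#' @param scenario An [erosion_scenario()].
#' @param substrate Substrate label attached to the curves (`"PCL"`,
#'   `"PET"`, ...).
#' @param temperature Assay temperature (°C) attached to the curves.
#' @param enzyme Enzyme label attached to the curves.
#' @return A list of [turbidity_curve()] objects (class
#'   `turbidity_curve_set`), one per concentration and replicate.
#' @examples
#' sc <- erosion_scenario(k_tau = 4.1e-3, K_A = 44.4,
#'                        enzyme_concs = c(0, 0.02, 0.08),
#'                        duration = 60, dt = 5)
#' curves <- simulate_turbidity_curves(sc, substrate = "PET", temperature = 50)
#' @export
simulate_turbidity_curves <- function(scenario, substrate = "PCL",
                                      temperature = 49, enzyme = "enzyme") {
  stopifnot(inherits(scenario, "erosion_scenario"))
  times <- seq(0, scenario$duration, by = scenario$dt)
  rates <- erosion_rate(scenario, scenario$enzyme_concs)
  curves <- with_seed(scenario$seed, {
    out <- list()
    for (i in seq_along(scenario$enzyme_concs)) {
      for (rep_id in seq_len(scenario$n_replicates)) {
        y <- pmax(0, 1 - rates[i] * times)
        tau <- scenario$tau0 * y^2
        if (scenario$noise_rel > 0)
          tau <- tau * (1 + stats::rnorm(length(tau), 0, scenario$noise_rel))
        tau <- pmax(tau, 0)
        # seed the first sample away from zero so sqrt-normalization is defined
        if (tau[1] <= 0) tau[1] <- scenario$tau0 * .Machine$double.eps
        out[[length(out) + 1L]] <- turbidity_curve(
          times = times, turbidity = tau,
          enzyme_conc = scenario$enzyme_concs[i],
          substrate = substrate, temperature = temperature,
          replicate = rep_id, enzyme = enzyme)
      }
    }
    out
  })
  structure(curves, class = "turbidity_curve_set")
}

#' Simulate an (enzyme concentration, initial rate) dataset directly
#'
#' Shortcut that emits `R(E)` plus multiplicative noise without synthesizing
#' full turbidity traces; convenient for Monte-Carlo studies of the
#' saturation fit.
#'
#' @inheritParams simulate_turbidity_curves
#' @return A [rate_dataset()] with one row per concentration and replicate.
#' @export
simulate_rate_dataset <- function(scenario, substrate = "PCL",
                                  temperature = 49, enzyme = "enzyme") {
  stopifnot(inherits(scenario, "erosion_scenario"))
  E <- rep(scenario$enzyme_concs, each = scenario$n_replicates)
  repl <- rep(seq_len(scenario$n_replicates), times = length(scenario$enzyme_concs))
  r0 <- rep(erosion_rate(scenario, scenario$enzyme_concs),
            each = scenario$n_replicates)
  rate <- with_seed(scenario$seed, {
    if (scenario$noise_rel > 0)
      pmax(0, r0 * (1 + stats::rnorm(length(r0), 0, scenario$noise_rel)))
    else r0
  })
  rate_dataset(E = E, rate = rate, replicate = repl,
               substrate = substrate, temperature = temperature,
               enzyme = enzyme)
}

#' Simulate Michaelis-Menten velocity data
#'
#' Velocities follow \eqn{v = k_{cat} E_0 S/(K_m + S)} with multiplicative
#' Gaussian noise.
#'
#' @param scenario An [mm_scenario()].
#' @return A data.frame with columns `S` (µM) and `v` (µM/s).
#' @export
simulate_mm_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "mm_scenario"))
  if (length(scenario$substrate_concs) == 0L)
    hk_stop_invalid("substrate_concs", "must be non-empty")
  S <- scenario$substrate_concs
  v0 <- scenario$k_cat * scenario$E0 * S / (scenario$K_m + S)
  v <- with_seed(scenario$seed, {
    if (scenario$noise_rel > 0)
      pmax(0, v0 * (1 + stats::rnorm(length(v0), 0, scenario$noise_rel)))
    else v0
  })
  data.frame(S = S, v = v)
}

#' Simulate residual-activity (thermal inactivation) data
#'
#' Activity fractions follow first-order decay \eqn{A(t) = e^{-k_d t}} with
#' additive Gaussian noise, clipped to `[0, 1.05]` (slightly above 1 to
#' mimic assay scatter around the initial activity).
#'
#' @param scenario A [decay_scenario()].
#' @return A data.frame with columns `time` (min) and `activity` (fraction
#'   of initial).
#' @export
simulate_decay_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "decay_scenario"))
  a0 <- exp(-scenario$k_d * scenario$times)
  a <- with_seed(scenario$seed, {
    if (scenario$noise_abs > 0)
      a0 + stats::rnorm(length(a0), 0, scenario$noise_abs)
    else a0
  })
  data.frame(time = scenario$times, activity = pmin(pmax(a, 0), 1.05))
}

# Uniform random proper rotation via QR of a Gaussian matrix with sign fix.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  Q <- Q %*% diag(sign(d + (d == 0)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Simulate a rigid-body-perturbed atomic trajectory
#'
#' Each frame is `reference + per-atom Gaussian displacement`, optionally
#' followed by a random global rotation and translation (the component a
#' superposition step must remove). Frame times are attached at `dt_ns`
#' spacing.
#'
#' @param scenario A [trajectory_scenario()].
#' @param atoms Optional atom metadata data.frame (see [trajectory()]);
#'   default labels every atom `CA` in consecutive `GLY` residues of chain
#'   `A`, so C-alpha selections resolve.
#' @return A [trajectory()] object.
#' @export
simulate_trajectory <- function(scenario, atoms = NULL) {
  stopifnot(inherits(scenario, "trajectory_scenario"))
  n <- scenario$n_atoms
  nf <- scenario$n_frames
  coords <- with_seed(scenario$seed, {
    arr <- array(NA_real_, dim = c(nf, n, 3))
    for (f in seq_len(nf)) {
      disp <- matrix(stats::rnorm(3 * n, 0, rep(scenario$per_atom_sigma, 3)),
                     nrow = n, ncol = 3)
      x <- scenario$reference_coords + disp
      if (scenario$rigid_motion) {
        R <- random_rotation()
        tr <- stats::rnorm(3, 0, 5)
        x <- x %*% R + matrix(tr, n, 3, byrow = TRUE)
      }
      arr[f, , ] <- x
    }
    arr
  })
  if (is.null(atoms))
    atoms <- data.frame(name = rep("CA", n), resno = seq_len(n),
                        resname = rep("GLY", n), chain = rep("A", n),
                        insert = rep("", n), stringsAsFactors = FALSE)
  trajectory(coords = coords,
             times = (seq_len(nf) - 1L) * scenario$dt_ns,
             atoms = atoms)
}
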