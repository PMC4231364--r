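# Shared fixtures and independent oracles.

# Published kinetic parameters used as generating truths in worked examples:
# adsorption-saturation constants (k_tau in 1/min, K_A in mL/mg) per
# enzyme/substrate/temperature, and Michaelis-Menten constants for pNPB
# (K_m in uM, k_cat in 1/s).
PCL49 <- list(Tcur1278 = c(k_tau = 122.2e-3, K_A = 41.1),
              Tcur0390 = c(k_tau = 108.3e-3, K_A = 96.0))
PET50 <- list(Tcur1278 = c(k_tau = 4.1e-3, K_A = 44.4),
              Tcur0390 = c(k_tau = 7.0e-3, K_A = 172.7))
MM_PNPB <- list(Tcur1278 = c(K_m = 88.8, k_cat = 2.3),
                Tcur0390 = c(K_m = 83.1, k_cat = 12.4))

# Closed-form two-point solution of R = k K E / (1 + K E) via the exact
# double-reciprocal system; independent of the fitting path.
sat_two_point <- function(E1, R1, E2, R2) {
  b <- (1 / R1 - 1 / R2) / (1 / E1 - 1 / E2)
  a <- 1 / R1 - b / E1
  c(k_tau = 1 / a, K_A = a / b)
}

# Closed-form two-point Michaelis-Menten solution from 1/v = 1/Vmax + (Km/Vmax)/S.
mm_two_point <- function(S1, v1, S2, v2) {
  b <- (1 / v1 - 1 / v2) / (1 / S1 - 1 / S2)  # Km/Vmax
  a <- 1 / v1 - b / S1                        # 1/Vmax
  c(V_max = 1 / a, K_m = b / a)
}

# Brute-force superposition oracle: minimum RMSD over a dense axis-angle
# rotation grid (centroids removed analytically).
brute_force_rmsd <- function(mobile, reference, n_axes = 400, angle_step = 2) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  # Fibonacci sphere of rotation axes
  i <- seq_len(n_axes) - 0.5
  phi <- acos(1 - 2 * i / n_axes)
  theta <- pi * (1 + sqrt(5)) * i
  axes <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  angles <- seq(0, pi, by = angle_step * pi / 180)
  best <- Inf
  for (a in seq_len(n_axes)) {
    u <- axes[a, ]
    ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    uu <- tcrossprod(u)
    for (ang in angles) {
      R <- cos(ang) * diag(3) + sin(ang) * ux + (1 - cos(ang)) * uu
      r <- sqrt(mean(rowSums((P %*% R - Q)^2)))
      if (r < best) best <- r
    }
  }
  best
}

random_proper_rotation <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(traj, R, tvec) {
  for (f in seq_len(dim(traj$coords)[1])) {
    x <- matrix(traj$coords[f, , ], ncol = 3)
    traj$coords[f, , ] <- x %*% R + matrix(tvec, nrow(x), 3, byrow = TRUE)
  }
  traj
}

noise_free_fit <- function(params, E_grid, ...) {
  sc <- erosion_scenario(k_tau = params[["k_tau"]], K_A = params[["K_A"]],
                         enzyme_concs = E_grid, ...)
  fit_saturation(simulate_rate_dataset(sc))
}
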