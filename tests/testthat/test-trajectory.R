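test_that("Kabsch superposition removes rigid motion and yields proper rotations", {
  set.seed(11)
  P <- matrix(rnorm(30), 10, 3)
  sp <- kabsch_superpose(P, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  for (i in 1:20) {
    R <- random_proper_rotation()
    tvec <- rnorm(3, 0, 10)
    Q <- P %*% R + matrix(tvec, nrow(P), 3, byrow = TRUE)
    sp <- kabsch_superpose(Q, P)
    expect_lt(sp$rmsd, 1e-8)
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  }

  # degenerate selections are refused
  line <- cbind(1:5, 2 * (1:5), -1:3 * 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear",
               class = "hydrokin_validation_error")
  expect_error(kabsch_superpose(P, P[1:5, ]), "mismatch",
               class = "hydrokin_validation_error")
})

test_that("Kabsch RMSD matches a brute-force rotation-grid oracle", {
  set.seed(21)
  for (i in 1:3) {
    A <- matrix(rnorm(15, sd = 1.5), 5, 3)
    B <- matrix(rnorm(15, sd = 1.5), 5, 3)
    ours <- kabsch_superpose(A, B)$rmsd
    grid <- brute_force_rmsd(A, B)
    expect_lte(ours, grid + 1e-10)   # ours is the optimum
    expect_lt(grid - ours, 0.1)      # grid approaches it at 2 deg resolution
  }
})

test_that("RMSD time series is zero for static or rigidly moving trajectories", {
  tr <- simulate_trajectory(trajectory_scenario(n_atoms = 8, n_frames = 15,
    per_atom_sigma = 0, rigid_motion = FALSE, seed = 2))
  expect_equal(rmsd_timeseries(tr, selection = "all")$rmsd, rep(0, 15),
               tolerance = 1e-10)
  trm <- simulate_trajectory(trajectory_scenario(n_atoms = 8, n_frames = 15,
    per_atom_sigma = 0, rigid_motion = TRUE, seed = 2))
  expect_lt(max(rmsd_timeseries(trm, selection = "all")$rmsd), 1e-8)
  expect_equal(rmsd_timeseries(trm, selection = "all")$rmsd[1], 0,
               tolerance = 1e-10)
  # nm output is Angstrom / 10
  tr2 <- simulate_trajectory(trajectory_scenario(n_atoms = 8, n_frames = 5,
    per_atom_sigma = 0.4, rigid_motion = FALSE, seed = 3))
  expect_equal(rmsd_timeseries(tr2, selection = "all", units = "nm")$rmsd,
               rmsd_timeseries(tr2, selection = "all")$rmsd / 10)
})

test_that("single displaced atom gives the brute-force RMSD on a toy system", {
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  moved <- ref
  moved[4, ] <- moved[4, ] + c(1.2, 0, 0)
  ours <- kabsch_superpose(moved, ref)$rmsd
  grid <- brute_force_rmsd(moved, ref)
  expect_lte(ours, grid + 1e-10)
  expect_lt(grid - ours, 0.05)
})

test_that("RMSD and distances are invariant under global rigid motion", {
  tr <- simulate_trajectory(trajectory_scenario(n_atoms = 10, n_frames = 10,
    per_atom_sigma = 0.5, rigid_motion = FALSE, seed = 5))
  set.seed(6)
  moved <- apply_rigid(tr, random_proper_rotation(), rnorm(3, 0, 20))
  expect_equal(rmsd_timeseries(moved, selection = "all")$rmsd,
               rmsd_timeseries(tr, selection = "all")$rmsd, tolerance = 1e-8)
  expect_equal(distance_timeseries(moved, "A:1:CA", "A:5:CA")$distance,
               distance_timeseries(tr, "A:1:CA", "A:5:CA")$distance,
               tolerance = 1e-8)
})

test_that("per-residue RMSF recovers the generating fluctuation", {
  # isotropic per-coordinate sigma: RMSF = sigma * sqrt(3)
  sigma <- 0.3
  tr <- simulate_trajectory(trajectory_scenario(n_atoms = 10, n_frames = 10000,
    per_atom_sigma = sigma, rigid_motion = FALSE, seed = 8))
  rf <- rmsf_per_residue(tr, superpose = FALSE)
  expect_equal(nrow(rf), 10)
  expect_equal(mean(rf$rmsf), sigma * sqrt(3), tolerance = 0.03)

  # static trajectory: all zeros
  tr0 <- simulate_trajectory(trajectory_scenario(n_atoms = 6, n_frames = 10,
    per_atom_sigma = 0, rigid_motion = FALSE, seed = 9))
  expect_equal(rmsf_per_residue(tr0)$rmsf, rep(0, 6), tolerance = 1e-10)

  # one atom alternating +/- d about its mean, superposition on the static rest
  d <- 0.8
  nf <- 20
  ref <- trajectory_scenario(n_atoms = 6, n_frames = nf,
                             per_atom_sigma = 0, rigid_motion = FALSE)$reference_coords
  coords <- array(rep(t(ref), nf), dim = c(3, 6, nf))
  coords <- aperm(coords, c(3, 2, 1))
  coords[, 6, 1] <- ref[6, 1] + d * rep(c(1, -1), nf / 2)
  tr1 <- trajectory(coords, times = seq_len(nf) - 1,
                    atoms = data.frame(name = "CA", resno = 1:6,
                                       resname = "GLY", chain = "A"))
  rf1 <- rmsf_per_residue(tr1, selection = "calpha", fit_selection = 1:5)
  expect_equal(rf1$rmsf[6], d, tolerance = 1e-10)
  expect_equal(rf1$rmsf[1:5], rep(0, 5), tolerance = 1e-10)
})

test_that("superposition-based RMSF matches the direct estimate for rigidly moving frames", {
  sigma <- 0.25
  tr <- simulate_trajectory(trajectory_scenario(n_atoms = 40, n_frames = 800,
    per_atom_sigma = sigma, rigid_motion = TRUE, seed = 12))
  rf <- rmsf_per_residue(tr)
  # superposition absorbs ~6/(3N) of the variance; negligible at N = 40
  expect_equal(mean(rf$rmsf), sigma * sqrt(3) * sqrt(1 - 6 / (3 * 40)),
               tolerance = 0.05)
})

test_that("atom-pair distances are Euclidean and specs must be unique", {
  coords <- array(0, dim = c(1, 3, 3))
  coords[1, 2, ] <- c(3, 4, 0)
  atoms <- data.frame(name = c("NE2", "OG", "CA"), resno = c(208, 130, 1),
                      resname = c("HIS", "SER", "GLY"), chain = "A")
  tr <- trajectory(coords, times = 0, atoms = atoms)
  expect_equal(distance_timeseries(tr, "A:208:NE2", "A:130:OG")$distance, 5)
  expect_equal(distance_timeseries(tr, "A:208:NE2", "A:1:CA")$distance, 0)
  expect_equal(distance_timeseries(tr, "A:208:NE2", "A:130:OG",
                                   units = "nm")$distance, 0.5)
  err <- tryCatch(distance_timeseries(tr, "A:*:*", "A:130:OG"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "ambiguous")
  expect_match(err, "HIS")   # candidates are listed
  expect_error(distance_timeseries(tr, "B:1:CA", "A:130:OG"), "no atom",
               class = "hydrokin_validation_error")
})

test_that("selection mini-language resolves keywords, patterns and wildcards", {
  atoms <- data.frame(name = c("N", "CA", "C", "O", "CB", "CA"),
                      resno = c(1, 1, 1, 1, 1, 2),
                      resname = c(rep("ALA", 5), "GLY"),
                      chain = c(rep("A", 5), "B"))
  tr <- trajectory(array(rnorm(18), c(1, 6, 3)), 0, atoms)
  expect_equal(select_atoms(tr, "backbone"), c(1:4, 6))
  expect_equal(select_atoms(tr, "calpha"), c(2, 6))
  expect_equal(select_atoms(tr, "A:1:CA"), 2)
  expect_equal(select_atoms(tr, "*:*:CA"), c(2, 6))
  expect_equal(select_atoms(tr, "B:*:*"), 6)
  expect_equal(select_atoms(tr, c(3, 5)), c(3L, 5L))
  expect_error(select_atoms(tr, "not a pattern"), "selection",
               class = "hydrokin_validation_error")
})
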