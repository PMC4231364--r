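test_that("turbidity simulator obeys the erosion model limits", {
  # zero enzyme: turbidity stays at tau0
  sc <- erosion_scenario(k_tau = 0.1, K_A = 50, enzyme_concs = 0,
                         tau0 = 0.5, noise_rel = 0)
  cv <- simulate_turbidity_curves(sc)[[1]]
  expect_equal(cv$turbidity, rep(0.5, length(cv$times)))

  # worked example: published PET/50C parameters at 0.08 mg/mL give an
  # initial sqrt-turbidity slope of k_tau * K_A E/(1 + K_A E) = 3.1993e-3/min
  p <- PET50$Tcur1278
  R_expected <- p[["k_tau"]] * p[["K_A"]] * 0.08 / (1 + p[["K_A"]] * 0.08)
  expect_equal(R_expected, 3.1993e-3, tolerance = 1e-4)
  sc <- erosion_scenario(p[["k_tau"]], p[["K_A"]], 0.08,
                         duration = 60, dt = 5)
  y <- sqrt_normalize(simulate_turbidity_curves(sc, substrate = "PET")[[1]])
  slopes <- -diff(y$y) / diff(y$time)
  expect_equal(slopes, rep(R_expected, length(slopes)), tolerance = 1e-12)

  # half-saturation by construction: E = 1/K_A gives slope k_tau/2
  sc <- erosion_scenario(k_tau = 0.02, K_A = 123, enzyme_concs = 1 / 123)
  y <- sqrt_normalize(simulate_turbidity_curves(sc)[[1]])
  expect_equal(-(y$y[2] - y$y[1]) / (y$time[2] - y$time[1]), 0.01,
               tolerance = 1e-12)
})

test_that("noise-free sqrt-turbidity is affine until depletion, then zero", {
  sc <- erosion_scenario(k_tau = 0.2, K_A = 1000, enzyme_concs = 0.1,
                         duration = 15, dt = 1)
  cv <- simulate_turbidity_curves(sc)[[1]]
  y <- sqrt_normalize(cv)
  R <- erosion <- predict_rate(0.2, 1000, 0.1)
  dep <- y$time < 1 / R
  expect_equal(y$y[dep], 1 - R * y$time[dep], tolerance = 1e-12)
  expect_true(any(!dep))  # depletion reached within the assay
  expect_equal(y$y[!dep], rep(0, sum(!dep)))
})

test_that("rate simulator is exact without noise and seeded with it", {
  p <- PCL49$Tcur1278
  grid <- seq(0.005, 0.08, length.out = 8)
  ds <- simulate_rate_dataset(erosion_scenario(p[["k_tau"]], p[["K_A"]], grid))
  expect_equal(ds$rate, predict_rate(p[["k_tau"]], p[["K_A"]], grid))
  # hand evaluation at 0.03 mg/mL with the PCL parameters
  expect_equal(predict_rate(p[["k_tau"]], p[["K_A"]], 0.03), 0.0675,
               tolerance = 1e-3)

  sc <- erosion_scenario(p[["k_tau"]], p[["K_A"]], grid, noise_rel = 0.03,
                         seed = 42)
  expect_identical(simulate_rate_dataset(sc)$rate,
                   simulate_rate_dataset(sc)$rate)
  sc2 <- erosion_scenario(p[["k_tau"]], p[["K_A"]], grid, noise_rel = 0.03,
                          seed = 43)
  expect_false(identical(simulate_rate_dataset(sc)$rate,
                         simulate_rate_dataset(sc2)$rate))
})

test_that("empirical noise s.d. of simulated rates matches noise_rel", {
  sc <- erosion_scenario(k_tau = 0.1, K_A = 50, enzyme_concs = 0.02,
                         noise_rel = 0.05, seed = 7, n_replicates = 20000L)
  ds <- simulate_rate_dataset(sc)
  R <- predict_rate(0.1, 50, 0.02)
  expect_equal(sd(ds$rate) / R, 0.05, tolerance = 0.05)
})

test_that("crowding inhibition reduces rates at high enzyme loads", {
  grid <- c(0.01, 0.05, 0.2, 0.5)
  base <- simulate_rate_dataset(erosion_scenario(0.1, 50, grid))
  crowd <- simulate_rate_dataset(erosion_scenario(0.1, 50, grid,
    crowding = list(threshold = 0.1, hill = 3)))
  expect_true(all(crowd$rate <= base$rate))
  # well below threshold the factor is ~1; above it, strongly suppressed
  expect_equal(crowd$rate[1], base$rate[1], tolerance = 1e-2)
  expect_lt(crowd$rate[4] / base$rate[4], 0.2)
  # with crowding the observed rate maximum sits at an interior concentration
  expect_lt(which.max(crowd$rate), length(grid))
})

test_that("Michaelis-Menten simulator honors saturation and half-velocity", {
  p <- MM_PNPB$Tcur1278
  d <- simulate_mm_dataset(mm_scenario(p[["K_m"]], p[["k_cat"]], E0 = 0.1,
                                       substrate_concs = p[["K_m"]] * c(1, 1e6)))
  expect_equal(d$v[1], p[["k_cat"]] * 0.1 / 2, tolerance = 1e-12)  # v = 0.115
  expect_equal(d$v[2] / (p[["k_cat"]] * 0.1), 1, tolerance = 1e-5)
})

test_that("decay simulator obeys first-order kinetics", {
  # k_d chosen to leave 40% residual activity after 60 min
  k_d <- log(2.5) / 60
  d <- simulate_decay_dataset(decay_scenario(k_d, times = c(0, 30, 60)))
  expect_equal(d$activity[3], 0.40, tolerance = 1e-12)
  expect_equal(d$activity[1], 1)
  # semigroup property A(t1) * A(t2) = A(t1 + t2)
  expect_equal(d$activity[2]^2, d$activity[3], tolerance = 1e-12)
  d0 <- simulate_decay_dataset(decay_scenario(0, times = c(0, 30, 60)))
  expect_equal(d0$activity, rep(1, 3))
})

test_that("trajectory simulator is seeded and respects sigma = 0", {
  sc <- trajectory_scenario(n_atoms = 6, n_frames = 20, per_atom_sigma = 0,
                            rigid_motion = TRUE, seed = 9)
  tr <- simulate_trajectory(sc)
  rs <- rmsd_timeseries(tr, selection = "all")
  expect_lt(max(rs$rmsd), 1e-8)
  expect_identical(simulate_trajectory(sc)$coords, tr$coords)
  sc2 <- trajectory_scenario(n_atoms = 6, n_frames = 20, per_atom_sigma = 0,
                             rigid_motion = TRUE, seed = 10)
  expect_false(identical(simulate_trajectory(sc2)$coords, tr$coords))
})

test_that("simulators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_rate_dataset(erosion_scenario(0.1, 50, 0.02,
                                                   noise_rel = 0.05, seed = 5)))
  expect_identical(.Random.seed, before)
})
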