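test_that("predict_rate is monotone, bounded and exact at landmarks", {
  expect_equal(predict_rate(0.1, 50, 0), 0)
  expect_equal(predict_rate(0.02, 123, 1 / 123), 0.01, tolerance = 1e-15)
  p <- PET50$Tcur1278
  expect_equal(predict_rate(p[["k_tau"]], p[["K_A"]], 0.08), 3.1993e-3,
               tolerance = 1e-4)
  expect_error(predict_rate(-1, 50, 0.1), "k_tau",
               class = "hydrokin_validation_error")
  for (i in 1:20) {
    k <- 10^runif(1, -4, 0); K <- 10^runif(1, 0, 3)
    E <- sort(runif(20, 0, 1))
    r <- predict_rate(k, K, E)
    expect_true(all(diff(r) > 0))
    expect_true(all(r < k))
    expect_equal(predict_rate(k, K, 1 / K), k / 2, tolerance = 1e-12)
  }
})

test_that("saturation fit recovers generating parameters exactly on noise-free data", {
  # worked example at the published PET/50C parameters
  f <- noise_free_fit(PET50$Tcur1278, seq(0.005, 0.08, length.out = 8))
  expect_true(f$converged)
  expect_equal(f$k_tau, 4.1e-3, tolerance = 1e-6)
  expect_equal(f$K_A, 44.4, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)

  # property sweep over the plausible parameter box
  for (i in 1:25) {
    k <- 10^runif(1, -4, 0); K <- 10^runif(1, 0, 3)
    grid <- 10^seq(log10(0.05 / K), log10(20 / K), length.out = 6)
    f <- noise_free_fit(c(k_tau = k, K_A = K), grid)
    expect_equal(f$k_tau, k, tolerance = 1e-6)
    expect_equal(f$K_A, K, tolerance = 1e-6)
  }
})

test_that("saturation fit agrees with the two-point closed-form oracle", {
  for (i in 1:100) {
    k <- 10^runif(1, -3, -1); K <- 10^runif(1, 0.5, 2.5)
    E <- sort(10^runif(4, log10(0.1 / K), log10(10 / K)))
    R <- predict_rate(k, K, E)
    oracle <- sat_two_point(E[1], R[1], E[3], R[3])
    f <- fit_saturation(data.frame(E = E, rate = R))
    expect_equal(f$k_tau, unname(oracle["k_tau"]), tolerance = 1e-6)
    expect_equal(f$K_A, unname(oracle["K_A"]), tolerance = 1e-6)
  }
})

test_that("stochastic recovery: median over seeded replicates is close to truth", {
  p <- PCL49$Tcur1278
  kt <- vapply(1:200, function(s) {
    sc <- erosion_scenario(p[["k_tau"]], p[["K_A"]],
                           seq(0.002, 0.03, length.out = 8),
                           noise_rel = 0.03, seed = s)
    fit_saturation(simulate_rate_dataset(sc))$k_tau
  }, numeric(1))
  expect_equal(median(kt), p[["k_tau"]], tolerance = 0.02)
})

test_that("fit is invariant to point order and duplication, with sensible errors", {
  p <- PCL49$Tcur0390
  grid <- seq(0.002, 0.02, length.out = 6)
  ds <- simulate_rate_dataset(erosion_scenario(p[["k_tau"]], p[["K_A"]], grid,
                                               noise_rel = 0.02, seed = 3))
  f1 <- fit_saturation(ds)
  shuffled <- ds[sample(nrow(ds)), ]
  f2 <- fit_saturation(shuffled)
  expect_equal(f1$k_tau, f2$k_tau, tolerance = 1e-6)
  expect_equal(f1$K_A, f2$K_A, tolerance = 1e-6)
  doubled <- rbind(as.data.frame(ds), as.data.frame(ds))
  f3 <- fit_saturation(doubled)
  expect_equal(f1$k_tau, f3$k_tau, tolerance = 1e-6)
  # duplication rescales the SE by sqrt((n-2)/(2n-2)) (dof-adjusted halving
  # of the parameter variance) without moving the estimate
  n <- f1$n_points_used
  expect_equal(f3$se_K_A / f1$se_K_A, sqrt((n - 2) / (2 * n - 2)),
               tolerance = 1e-6)

  expect_error(fit_saturation(data.frame(E = c(0.01, 0.02), rate = c(1, 2))),
               "3 distinct", class = "hydrokin_fit_error")
  expect_error(fit_saturation(data.frame(E = c(0.01, 0.02, 0.04),
                                         rate = c(0, 0, 0))),
               "unidentifiable", class = "hydrokin_fit_error")
})

test_that("supra-maximal concentrations are excluded by default and logged", {
  p <- c(k_tau = 0.1, K_A = 50)
  grid <- c(0.005, 0.01, 0.02, 0.04, 0.08, 0.16)
  ds <- simulate_rate_dataset(erosion_scenario(p[["k_tau"]], p[["K_A"]], grid,
    crowding = list(threshold = 0.05, hill = 4)))
  f <- fit_saturation(ds)
  expect_true(length(f$excluded_points) >= 1)
  expect_true(all(ds$E[f$excluded_points] > ds$E[which.max(ds$rate)]))
  f_all <- fit_saturation(ds, exclude_supramaximal = FALSE)
  expect_length(f_all$excluded_points, 0)
  expect_equal(f_all$n_points_used, length(grid))
  # excluding the crowded points moves the fit toward the generating truth
  expect_lt(abs(f$k_tau - p[["k_tau"]]), abs(f_all$k_tau - p[["k_tau"]]))
})

test_that("inverse-variance weighting is supported and validated", {
  ds <- rate_dataset(E = c(0.01, 0.02, 0.04, 0.08),
                     rate = c(0.03, 0.05, 0.07, 0.08),
                     rate_se = c(0.002, 0.002, 0.004, 0.008))
  fw <- fit_saturation(ds, weighting = "inverse_se2")
  expect_true(fw$converged)
  expect_error(
    fit_saturation(rate_dataset(E = c(0.01, 0.02, 0.04), rate = c(1, 2, 2.5)),
                   weighting = "inverse_se2"),
    "rate_se", class = "hydrokin_validation_error")
})

test_that("fold changes reproduce the published enzyme comparisons", {
  grid_pet <- seq(0.005, 0.08, length.out = 8)
  f1278 <- noise_free_fit(PET50$Tcur1278, grid_pet)
  f0390 <- noise_free_fit(PET50$Tcur0390, seq(0.002, 0.02, length.out = 8))
  fc <- fold_change(f1278, f0390)
  expect_equal(fc$k_tau_ratio_2sf, 1.7)
  expect_equal(fc$K_A_ratio_2sf, 3.9)

  p1 <- noise_free_fit(PCL49$Tcur1278, seq(0.002, 0.03, length.out = 8))
  p0 <- noise_free_fit(PCL49$Tcur0390, seq(0.002, 0.02, length.out = 8))
  expect_equal(fold_change(p1, p0)$K_A_ratio_2sf, 2.3)

  id <- fold_change(f1278, f1278)
  expect_equal(id$k_tau_ratio, 1)
  expect_equal(id$K_A_ratio, 1)
})
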