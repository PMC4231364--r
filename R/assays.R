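#' Fit the Michaelis-Menten model to velocity data
#'
#' Nonlinear least squares of \eqn{v = V_{max} S/(K_m + S)} with starting
#' values from the Lineweaver-Burk regression
#' \eqn{1/v = 1/V_{max} + (K_m/V_{max})(1/S)}; Levenberg-Marquardt
#' refinement; Gauss-Newton covariance. When `E0` is supplied the turnover
#' number `k_cat = V_max / E0` is reported alongside.
#'
#' Identifiability: when the substrate grid does not bracket `K_m` the two
#' parameters become nearly collinear; this is flagged (not an error) via
#' the condition number of the scaled Jacobian in
#' `identifiability_warning`.
#'
#' @param S Substrate concentrations (µM), > 0, at least 4 points over at
#'   least 3 distinct values.
#' @param v Velocities (µM/s), >= 0.
#' @param E0 Optional enzyme concentration (µM) for `k_cat`.
#' @return An object of class `mm_fit` with `K_m`, `V_max`, `k_cat`, SEs,
#'   `covariance`, `r_squared`, `converged`, `identifiability_warning`.
#' @examples
#' d <- simulate_mm_dataset(mm_scenario(K_m = 88.8, k_cat = 2.3, E0 = 0.1,
#'                                      substrate_concs = c(10, 30, 100, 300, 1000)))
#' fit_michaelis_menten(d$S, d$v, E0 = 0.1)
#' @export
fit_michaelis_menten <- function(S, v, E0 = NULL) {
  check_numeric_vec(S, "S", positive = TRUE, min_len = 4L)
  check_numeric_vec(v, "v", nonneg = TRUE, min_len = length(S))
  if (length(v) != length(S))
    hk_stop_invalid("v", "must have the same length as S")
  if (length(unique(S)) < 3L)
    hk_stop_invalid("S", "need at least 3 distinct substrate concentrations")
  # Lineweaver-Burk initializer on positive velocities
  ok <- v > 0
  init <- if (sum(ok) >= 2L) {
    lb <- stats::lm(I(1 / v[ok]) ~ I(1 / S[ok]))
    a <- stats::coef(lb)[1]; b <- stats::coef(lb)[2]
    if (is.finite(a) && a > 0 && is.finite(b) && b > 0)
      list(V_max = unname(1 / a), K_m = unname(b / a))
    else list(V_max = 1.1 * max(v), K_m = stats::median(S))
  } else list(V_max = 1.1 * max(v), K_m = stats::median(S))
  df <- data.frame(S = S, v = v)
  fit <- try(minpack.lm::nlsLM(
    v ~ V_max * S / (K_m + S), data = df,
    start = init, lower = c(0, 0),
    control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-12,
                                         maxiter = 200)),
    silent = TRUE)
  out <- list(K_m = NA_real_, V_max = NA_real_, k_cat = NA_real_,
              se_K_m = NA_real_, se_V_max = NA_real_, se_k_cat = NA_real_,
              covariance = matrix(NA_real_, 2, 2,
                dimnames = list(c("V_max", "K_m"), c("V_max", "K_m"))),
              r_squared = NA_real_, E0 = E0, converged = FALSE,
              identifiability_warning = NULL)
  class(out) <- "mm_fit"
  if (inherits(fit, "try-error")) {
    out$diagnostics <- attr(fit, "condition")$message
    return(out)
  }
  cf <- stats::coef(fit)
  vc <- try(stats::vcov(fit), silent = TRUE)
  if (inherits(vc, "try-error")) vc <- matrix(NA_real_, 2, 2)
  dimnames(vc) <- list(names(cf), names(cf))
  out$V_max <- unname(cf["V_max"]); out$K_m <- unname(cf["K_m"])
  out$se_V_max <- sqrt(vc["V_max", "V_max"])
  out$se_K_m <- sqrt(vc["K_m", "K_m"])
  out$covariance <- vc
  vhat <- out$V_max * S / (out$K_m + S)
  ss_res <- sum((v - vhat)^2)
  ss_tot <- sum((v - mean(v))^2)
  out$r_squared <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  out$converged <- is.finite(out$V_max) && is.finite(out$K_m) &&
    out$V_max > 0 && out$K_m >= 0
  if (!is.null(E0)) {
    check_scalar(E0, "E0", positive = TRUE)
    out$k_cat <- out$V_max / E0
    out$se_k_cat <- out$se_V_max / E0
  }
  # scaled-Jacobian condition number: dv/dVmax = S/(Km+S), dv/dKm = -Vmax S/(Km+S)^2
  # (K_m column scaled by K_m/V_max so both columns are relative sensitivities)
  J <- cbind(S / (out$K_m + S),
             -out$V_max * S / (out$K_m + S)^2 * out$K_m / out$V_max)
  d <- tryCatch(svd(J)$d, error = function(e) c(1, 0))
  kappa_ <- if (length(d) < 2 || d[2] <= 0 || !all(is.finite(d))) Inf else d[1] / d[2]
  if (!is.finite(kappa_) || kappa_ > 1e6)
    out$identifiability_warning <- sprintf(
      "substrate grid poorly brackets K_m (scaled Jacobian condition number %.3g)",
      kappa_)
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit: v = V_max * S / (K_m + S)\n")
  cat(sprintf("  K_m   = %.4g +/- %.2g uM\n", x$K_m, x$se_K_m))
  cat(sprintf("  V_max = %.4g +/- %.2g uM/s\n", x$V_max, x$se_V_max))
  if (!is.na(x$k_cat))
    cat(sprintf("  k_cat = %.4g +/- %.2g 1/s (E0 = %g uM)\n",
                x$k_cat, x$se_k_cat, x$E0))
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  if (!is.null(x$identifiability_warning))
    cat("  warning:", x$identifiability_warning, "\n")
  invisible(x)
}

#' Fit first-order thermal inactivation to residual-activity data
#'
#' Models the remaining activity fraction as \eqn{A(t) = e^{-k_d t}}.
#' The rate constant is initialized by intercept-free least squares on
#' \eqn{\log A} and refined by nonlinear least squares on the original
#' scale; the half-life is \eqn{t_{1/2} = \ln 2 / k_d} (infinite when
#' `k_d` is 0).
#'
#' @param times Incubation times (min), >= 3 points.
#' @param residual_fractions Remaining activity fractions, each in
#'   (0, 1.05].
#' @return An object of class `decay_fit` with `k_d`, `half_life`,
#'   `se_k_d`, `r_squared`.
#' @export
fit_decay <- function(times, residual_fractions) {
  check_numeric_vec(times, "times", nonneg = TRUE, min_len = 3L)
  if (length(residual_fractions) != length(times))
    hk_stop_invalid("residual_fractions", "must have the same length as times")
  bad <- which(!is.finite(residual_fractions) | residual_fractions <= 0 |
                 residual_fractions > 1.05)
  if (length(bad))
    hk_stop_invalid("residual_fractions", sprintf(
      "values must lie in (0, 1.05]; offending rows: %s",
      paste(bad, collapse = ", ")))
  A <- residual_fractions
  # intercept-free log-linear initializer (A(0) = 1 by definition)
  k0 <- if (sum(times^2) > 0) max(0, -sum(times * log(A)) / sum(times^2)) else 0
  df <- data.frame(t = times, A = A)
  fit <- try(minpack.lm::nlsLM(
    A ~ exp(-k_d * t), data = df, start = list(k_d = k0), lower = 0,
    control = minpack.lm::nls.lm.control(ptol = 1e-12, ftol = 1e-14,
                                         maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    k_d <- k0; se <- NA_real_
  } else {
    k_d <- unname(stats::coef(fit)["k_d"])
    vc <- try(stats::vcov(fit), silent = TRUE)
    se <- if (inherits(vc, "try-error")) NA_real_ else sqrt(vc[1, 1])
  }
  Ahat <- exp(-k_d * times)
  ss_res <- sum((A - Ahat)^2)
  ss_tot <- sum((A - mean(A))^2)
  structure(list(
    k_d = k_d,
    half_life = if (k_d > 0) log(2) / k_d else Inf,
    se_k_d = se,
    r_squared = if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("First-order inactivation fit: A(t) = exp(-k_d t)\n")
  cat(sprintf("  k_d = %.4g +/- %.2g 1/min; t1/2 = %.4g min; R^2 = %.4f\n",
              x$k_d, x$se_k_d, x$half_life, x$r_squared))
  invisible(x)
}

#' Descriptive pH / temperature activity profile
#'
#' Normalizes an activity grid to its maximum, reports the optimum (the
#' grid point of maximal activity) and exposes linear interpolation of the
#' relative activity at arbitrary points. Purely descriptive: no smoothing
#' or model is applied.
#'
#' @param x Grid of pH values or temperatures (°C), >= 3 points; sorted
#'   with a warning if unordered.
#' @param activity Measured activities, >= 0, max > 0.
#' @return An object of class `activity_profile` with fields `x`,
#'   `activity` (normalized to max 1), `optimum`, and a function
#'   `fraction_at(x0)`.
#' @export
profile_summary <- function(x, activity) {
  check_numeric_vec(x, "x", min_len = 3L)
  check_numeric_vec(activity, "activity", nonneg = TRUE, min_len = length(x))
  if (length(activity) != length(x))
    hk_stop_invalid("activity", "must have the same length as x")
  if (max(activity) <= 0)
    hk_stop_invalid("activity", "maximum activity must be > 0")
  if (is.unsorted(x)) {
    warning("x grid not increasing; sorting", call. = FALSE)
    o <- order(x)
    x <- x[o]; activity <- activity[o]
  }
  rel <- activity / max(activity)
  obj <- list(x = x, activity = rel, optimum = x[which.max(rel)])
  obj$fraction_at <- function(x0)
    stats::approx(x, rel, xout = x0, rule = 1)$y
  structure(obj, class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("Activity profile over [%g, %g]: optimum at %g (relative activity 1)\n",
              min(x$x), max(x$x), x$optimum))
  invisible(x)
}
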