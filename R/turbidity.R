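#' Turbidity trace with condition metadata
#'
#' @param times Sampling times (min), strictly increasing.
#' @param turbidity Absorbance values (600 nm), >= 0; the first value must
#'   be positive so normalization is defined.
#' @param enzyme_conc Enzyme concentration (mg/mL).
#' @param substrate Substrate label (`"PCL"`, `"PET"`, ...).
#' @param temperature Assay temperature (°C).
#' @param replicate Replicate identifier.
#' @param enzyme Enzyme label.
#' @return An object of class `turbidity_curve`.
#' @export
turbidity_curve <- function(times, turbidity, enzyme_conc,
                            substrate = "PCL", temperature = NA_real_,
                            replicate = 1L, enzyme = "enzyme") {
  check_numeric_vec(times, "times", min_len = 2L)
  if (is.unsorted(times, strictly = TRUE))
    hk_stop_invalid("times", "must be strictly increasing")
  check_numeric_vec(turbidity, "turbidity", nonneg = TRUE, min_len = 2L)
  if (length(turbidity) != length(times))
    hk_stop_invalid("turbidity", "must have the same length as times")
  if (turbidity[1] <= 0)
    hk_stop_invalid("turbidity", "first value must be > 0")
  check_scalar(enzyme_conc, "enzyme_conc", nonneg = TRUE)
  structure(list(times = times, turbidity = turbidity,
                 enzyme_conc = enzyme_conc, substrate = substrate,
                 temperature = temperature, replicate = replicate,
                 enzyme = enzyme),
            class = "turbidity_curve")
}

#' @export
print.turbidity_curve <- function(x, ...) {
  cat(sprintf(
    "Turbidity curve: %s, %s, %g mg/mL, %g degC, replicate %s\n  %d samples over %g min, tau0 = %g\n",
    x$enzyme, x$substrate, x$enzyme_conc, x$temperature,
    as.character(x$replicate), length(x$times), max(x$times), x$turbidity[1]))
  invisible(x)
}

#' Normalize a turbidity trace to the square-root scale
#'
#' Returns \eqn{y(t) = \sqrt{\tau(t)/\tau(0)}}, the observable whose initial
#' slope defines the degradation rate: under the shrinking-particle model
#' \eqn{\sqrt\tau} is proportional to the particle radius, so `y` decreases
#' linearly during the initial phase. `y(0)` is exactly 1 and the transform
#' is invariant to rescaling the trace.
#'
#' @param curve A [turbidity_curve()].
#' @return A data.frame with columns `time` and `y`.
#' @export
sqrt_normalize <- function(curve) {
  stopifnot(inherits(curve, "turbidity_curve"))
  if (curve$turbidity[1] <= 0)
    hk_stop_invalid("turbidity", "tau(0) must be > 0 for normalization")
  data.frame(time = curve$times,
             y = sqrt(curve$turbidity / curve$turbidity[1]))
}

#' Initial-rate window policies
#'
#' `window_fixed(t_max)` uses all samples with `time <= t_max` (the default
#' `Inf` takes the full trace, matching assay protocols that are sampled
#' only over the initial phase, e.g. 15 min at 1-min steps for PCL or
#' 60 min at 5-min steps for PET). `window_auto()` instead takes the
#' longest prefix of at least `min_points` samples whose linear fit has
#' \eqn{R^2 \ge} `r2`, guarding against traces that run into depletion.
#'
#' @param t_max Window end (min) for the fixed policy.
#' @param r2 Minimum linear-fit R-squared for the automatic policy.
#' @param min_points Minimum samples in the window.
#' @return A window-policy object for [estimate_initial_rate()].
#' @export
window_fixed <- function(t_max = Inf, min_points = 4L) {
  structure(list(type = "fixed", t_max = t_max,
                 min_points = as.integer(min_points)),
            class = "hk_window_policy")
}

#' @rdname window_fixed
#' @export
window_auto <- function(r2 = 0.98, min_points = 4L) {
  structure(list(type = "auto", r2 = r2, min_points = as.integer(min_points)),
            class = "hk_window_policy")
}

ols_slope <- function(t, y) {
  fit <- stats::lm(y ~ t)
  # noise-free traces fit exactly; summary.lm warns about it, harmlessly
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       se = unname(sm$coefficients[2, 2]),
       r2 = sm$r.squared)
}

#' Estimate the initial degradation rate of a turbidity trace
#'
#' Fits an ordinary least-squares line to \eqn{y(t)=\sqrt{\tau/\tau_0}} on
#' the selected initial window and reports the (non-negative) magnitude of
#' its negative slope, in 1/min, together with the standard error of the
#' slope and the window actually used.
#'
#' @param curve A [turbidity_curve()].
#' @param window_policy A [window_fixed()] or [window_auto()] policy.
#' @return A list with elements `rate`, `se`, and `window_used`
#'   (`t_start`, `t_end`, `n_points`).
#' @export
estimate_initial_rate <- function(curve, window_policy = window_fixed()) {
  stopifnot(inherits(curve, "turbidity_curve"),
            inherits(window_policy, "hk_window_policy"))
  yt <- sqrt_normalize(curve)
  mp <- window_policy$min_points
  if (nrow(yt) < mp)
    hk_stop_invalid("times", sprintf("need at least %d samples", mp))
  if (length(unique(yt$time)) < 2L)
    hk_stop_invalid("times", "all sampling times identical")
  if (window_policy$type == "fixed") {
    keep <- which(yt$time <= window_policy$t_max)
    if (length(keep) < mp)
      hk_stop_invalid("window_policy",
        sprintf("fewer than %d samples inside the fixed window", mp))
    n_used <- length(keep)
    fit <- ols_slope(yt$time[keep], yt$y[keep])
  } else {
    n_used <- mp
    fit <- ols_slope(yt$time[1:mp], yt$y[1:mp])
    n <- mp
    while (n < nrow(yt)) {
      cand <- ols_slope(yt$time[1:(n + 1L)], yt$y[1:(n + 1L)])
      if (is.na(cand$r2) || cand$r2 < window_policy$r2) break
      n <- n + 1L
      fit <- cand
      n_used <- n
    }
  }
  list(rate = max(0, -fit$slope), se = fit$se,
       window_used = list(t_start = yt$time[1], t_end = yt$time[n_used],
                          n_points = n_used))
}

#' Initial-rate dataset for saturation fitting
#'
#' Tidy container for (enzyme concentration, initial rate) points feeding
#' [fit_saturation()].
#'
#' @param E Enzyme concentrations (mg/mL), >= 0.
#' @param rate Initial rates of sqrt-turbidity decrease (1/min), >= 0.
#' @param rate_se Optional standard errors of the rates (1/min).
#' @param replicate Optional replicate ids; duplicate `E` values are only
#'   allowed across distinct replicates.
#' @param n_replicates Replicates behind each point (after averaging).
#' @param substrate,temperature,enzyme Condition metadata.
#' @return An object of class `rate_dataset` (a data.frame with attributes).
#' @export
rate_dataset <- function(E, rate, rate_se = NA_real_, replicate = NULL,
                         n_replicates = 1L, substrate = "PCL",
                         temperature = NA_real_, enzyme = "enzyme") {
  check_numeric_vec(E, "E", nonneg = TRUE)
  check_numeric_vec(rate, "rate", nonneg = TRUE, min_len = length(E))
  if (length(rate) != length(E))
    hk_stop_invalid("rate", "must have the same length as E")
  if (is.null(replicate)) replicate <- rep(1L, length(E))
  if (anyDuplicated(paste(replicate, E)))
    hk_stop_invalid("E", "duplicate concentrations within a replicate group")
  df <- data.frame(E = E, rate = rate, rate_se = rate_se,
                   replicate = replicate, n_replicates = n_replicates)
  structure(df, class = c("rate_dataset", "data.frame"),
            substrate = substrate, temperature = temperature,
            enzyme = enzyme)
}

#' Build a rate dataset from a set of turbidity curves
#'
#' Estimates the initial rate of every curve and averages replicates at the
#' same enzyme concentration; the reported `rate_se` is the standard error
#' across replicates when more than one is present, else the OLS slope SE.
#'
#' @param curves A list of [turbidity_curve()] objects.
#' @param window_policy Passed to [estimate_initial_rate()].
#' @return A [rate_dataset()].
#' @export
rates_from_curves <- function(curves, window_policy = window_fixed()) {
  stopifnot(length(curves) >= 1L)
  per <- lapply(curves, function(cv) {
    r <- estimate_initial_rate(cv, window_policy)
    data.frame(E = cv$enzyme_conc, rate = r$rate, se = r$se)
  })
  per <- do.call(rbind, per)
  agg <- lapply(split(per, per$E), function(d) {
    n <- nrow(d)
    se <- if (n > 1) stats::sd(d$rate) / sqrt(n) else d$se[1]
    data.frame(E = d$E[1], rate = mean(d$rate), rate_se = se, n = n)
  })
  agg <- do.call(rbind, agg)
  agg <- agg[order(agg$E), , drop = FALSE]
  first <- curves[[1]]
  rate_dataset(E = agg$E, rate = agg$rate, rate_se = agg$rate_se,
               n_replicates = agg$n, substrate = first$substrate,
               temperature = first$temperature, enzyme = first$enzyme)
}
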