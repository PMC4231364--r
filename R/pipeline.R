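# End-to-end workflow: turbidity curves -> initial rates -> saturation fits
# -> serialized report, with per-condition failure isolation and structured
# logging of window/exclusion decisions.

.hk_log_levels <- c(DEBUG = 10, INFO = 20, WARN = 30, ERROR = 40)

hk_log <- function(level, stage, msg, threshold = getOption("hydrokin.log_level", "INFO")) {
  if (.hk_log_levels[[level]] >= .hk_log_levels[[threshold]])
    message(sprintf("[%s] %s: %s", level, stage, msg))
  invisible(NULL)
}

#' Pipeline run configuration
#'
#' @param input Either a path to a turbidity CSV or a list of
#'   [turbidity_curve()] objects.
#' @param map A [condition_map()] (required when `input` is a path).
#' @param window_policy A [window_fixed()] or [window_auto()] policy.
#' @param weighting Passed to [fit_saturation()].
#' @param exclude_supramaximal Passed to [fit_saturation()].
#' @param seed Integer seed recorded in provenance.
#' @param outdir Optional directory for the JSON report and tidy CSVs.
#' @param log_level `"DEBUG"`, `"INFO"`, `"WARN"` or `"ERROR"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, map = NULL, window_policy = window_fixed(),
                       weighting = "none", exclude_supramaximal = TRUE,
                       seed = 1L, outdir = NULL, log_level = "INFO") {
  if (is.character(input)) {
    if (!file.exists(input))
      hk_stop_invalid("input", sprintf("file '%s' does not exist", input))
    if (is.null(map))
      hk_stop_invalid("map", "a condition_map is required for CSV input")
  }
  if (!log_level %in% names(.hk_log_levels))
    hk_stop_invalid("log_level", "must be DEBUG, INFO, WARN or ERROR")
  check_scalar(seed, "seed")
  structure(list(input = input, map = map, window_policy = window_policy,
                 weighting = weighting,
                 exclude_supramaximal = isTRUE(exclude_supramaximal),
                 seed = as.integer(seed), outdir = outdir,
                 log_level = log_level),
            class = "run_config")
}

config_hash <- function(config) {
  desc <- list(
    input = if (is.character(config$input)) config$input else "in-memory curves",
    n_curves = if (is.character(config$input)) NA_integer_ else length(config$input),
    map = if (is.null(config$map)) NULL else as.data.frame(config$map),
    window_policy = unclass(config$window_policy),
    weighting = config$weighting,
    exclude_supramaximal = config$exclude_supramaximal,
    seed = config$seed)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(desc, tf, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}

condition_key <- function(enzyme, substrate, temperature) {
  sprintf("%s:%s:%g", enzyme, substrate, temperature)
}

#' Run the full turbidimetric-kinetics pipeline
#'
#' Reads (or accepts) turbidity curves, estimates the initial
#' sqrt-turbidity degradation rate of every curve, groups curves by
#' (enzyme, substrate, temperature), averages replicates, fits the
#' adsorption-saturation model per condition and assembles a serializable
#' report. Conditions fail independently: a fit error marks that condition
#' failed and leaves the others untouched.
#'
#' @param config A [run_config()].
#' @return An object of class `fit_report`: list with `fits` (named by
#'   `enzyme:substrate:temperature`), `rates` (tidy data.frame of all rate
#'   points), `failures`, and `provenance` (config hash, seed, package
#'   version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  old <- options(hydrokin.log_level = config$log_level)
  on.exit(options(old))
  curves <- if (is.character(config$input)) {
    hk_log("INFO", "read", sprintf("reading turbidity CSV '%s'", config$input))
    read_turbidity_csv(config$input, config$map)
  } else config$input
  if (!length(curves)) hk_stop_invalid("input", "no curves to analyze")
  key <- vapply(curves, function(cv)
    condition_key(cv$enzyme, cv$substrate, cv$temperature), character(1))
  groups <- split(seq_along(curves), key)
  fits <- list(); failures <- list(); rate_rows <- list()
  for (k in names(groups)) {
    grp <- curves[groups[[k]]]
    res <- tryCatch({
      ds <- rates_from_curves(grp, config$window_policy)
      for (i in seq_len(nrow(ds)))
        hk_log("INFO", "rates", sprintf(
          "%s: E = %g mg/mL -> rate %.4g 1/min (n = %d)",
          k, ds$E[i], ds$rate[i], ds$n_replicates[i]))
      fit <- fit_saturation(ds, weighting = config$weighting,
                            exclude_supramaximal = config$exclude_supramaximal)
      if (length(fit$excluded_points))
        hk_log("INFO", "fit", sprintf(
          "%s: excluded supra-maximal point(s) at E = %s mg/mL", k,
          paste(ds$E[fit$excluded_points], collapse = ", ")))
      list(fit = fit, rates = ds)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      hk_log("WARN", "fit", sprintf("condition %s failed: %s", k,
                                    conditionMessage(res)))
      failures[[k]] <- conditionMessage(res)
    } else {
      fits[[k]] <- res$fit
      df <- as.data.frame(res$rates)
      df$condition <- k
      rate_rows[[k]] <- df
    }
  }
  structure(list(
    fits = fits,
    rates = if (length(rate_rows)) do.call(rbind, c(rate_rows, make.row.names = FALSE)) else NULL,
    failures = failures,
    provenance = list(config_hash = config_hash(config), seed = config$seed,
                      package_version = as.character(utils::packageVersion("hydrokin")))
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Fit report: %d condition(s) fitted, %d failed\n",
              length(x$fits), length(x$failures)))
  for (k in names(x$fits))
    cat(sprintf("  %s: k_tau = %.4g 1/min, K_A = %.4g mL/mg (R^2 %.3f)\n",
                k, x$fits[[k]]$k_tau, x$fits[[k]]$K_A, x$fits[[k]]$r_squared))
  for (k in names(x$failures)) cat(sprintf("  %s: FAILED (%s)\n", k, x$failures[[k]]))
  invisible(x)
}

report_payload <- function(report) {
  list(
    fits = lapply(report$fits, function(f) list(
      k_tau = f$k_tau, K_A = f$K_A, se_k_tau = f$se_k_tau, se_K_A = f$se_K_A,
      covariance = f$covariance, r_squared = f$r_squared,
      n_points_used = f$n_points_used,
      excluded_points = as.integer(f$excluded_points),
      converged = f$converged)),
    rates = report$rates,
    failures = report$failures,
    provenance = report$provenance)
}

#' Serialize / reload a fit report
#'
#' The JSON payload is written at full numeric precision and contains no
#' timestamps, so identical runs produce byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output JSON path.
#' @return `path` (write) / a list mirroring the report payload (read).
#' @export
write_fit_report <- function(report, path) {
  stopifnot(inherits(report, "fit_report"))
  jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Fold-change table between fitted conditions
#'
#' @param report A [run_pipeline()] result.
#' @param pairs List of 2-element character vectors
#'   `c(denominator_key, numerator_key)` naming report conditions
#'   (`enzyme:substrate:temperature`).
#' @return data.frame with full-precision and 2-significant-figure ratios.
#' @export
fold_change_report <- function(report, pairs) {
  stopifnot(inherits(report, "fit_report"))
  rows <- lapply(pairs, function(p) {
    if (length(p) != 2L)
      hk_stop_invalid("pairs", "each pair must name two conditions")
    for (k in p)
      if (is.null(report$fits[[k]]))
        hk_stop_invalid("pairs", sprintf(
          "condition '%s' is missing from the report (available: %s)", k,
          paste(names(report$fits), collapse = ", ")))
    fc <- fold_change(report$fits[[p[1]]], report$fits[[p[2]]])
    data.frame(denominator = p[1], numerator = p[2],
               k_tau_ratio = fc$k_tau_ratio, K_A_ratio = fc$K_A_ratio,
               k_tau_ratio_2sf = fc$k_tau_ratio_2sf,
               K_A_ratio_2sf = fc$K_A_ratio_2sf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
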