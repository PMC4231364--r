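# Internal helpers shared across modules.

# Validation failure tied to a named field; condition class lets callers
# (and the CLI, which maps it to exit code 2) distinguish bad input from
# numerical failure.
hk_stop_invalid <- function(field, msg, call. = FALSE) {
  stop(structure(
    class = c("hydrokin_validation_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = NULL)
  ))
}

hk_stop_fit <- function(msg) {
  stop(structure(
    class = c("hydrokin_fit_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    hk_stop_invalid(field, "must be a single non-missing number")
  if (finite && !is.finite(x))
    hk_stop_invalid(field, "must be finite")
  if (positive && x <= 0)
    hk_stop_invalid(field, "must be > 0")
  if (nonneg && x < 0)
    hk_stop_invalid(field, "must be >= 0")
  invisible(x)
}

check_numeric_vec <- function(x, field, nonneg = FALSE, positive = FALSE,
                              min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len || anyNA(x))
    hk_stop_invalid(field, sprintf(
      "must be a numeric vector of length >= %d with no missing values", min_len))
  if (nonneg && any(x < 0))
    hk_stop_invalid(field, "must be >= 0 elementwise")
  if (positive && any(x <= 0))
    hk_stop_invalid(field, "must be > 0 elementwise")
  invisible(x)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulators are reproducible without side effects.
with_seed <- function(seed, expr) {
  check_scalar(seed, "seed")
  if (abs(seed - round(seed)) > 0)
    hk_stop_invalid("seed", "must be an integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Enzyme concentration unit handling; canonical internal unit is mg/mL so
# that K_A * [E] is dimensionless (K_A in mL/mg).
convert_conc <- function(value, unit) {
  u <- tolower(gsub("[^a-z/]", "", tolower(unit)))
  factor <- switch(u,
    "mg/ml" = 1,
    "ug/ml" = 1e-3,
    "µg/ml" = 1e-3,
    hk_stop_invalid("conc_unit",
      sprintf("unknown unit '%s' (use mg/mL or ug/mL)", unit))
  )
  value * factor
}

`%||%` <- function(a, b) if (is.null(a)) b else a
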