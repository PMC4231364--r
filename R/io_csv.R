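# CSV interchange. Dialect: comma-separated, UTF-8, '.' decimal, mandatory
# header row, '#' comment lines. First column of a turbidity file is time
# in minutes; every other column is one assay condition.

#' Condition map for turbidity CSV columns
#'
#' Maps data columns of a turbidity CSV onto assay conditions. Enzyme
#' concentrations may be given in `mg/mL` or `ug/mL` (explicit unit tag);
#' the canonical internal unit is mg/mL, so that `K_A * E` is
#' dimensionless with `K_A` in mL/mg.
#'
#' @param column Column names in the CSV.
#' @param enzyme_conc Enzyme concentration per column.
#' @param conc_unit Unit of `enzyme_conc` (`"mg/mL"` or `"ug/mL"`).
#' @param substrate,temperature,enzyme,replicate Condition metadata per
#'   column (recycled if scalar).
#' @return A `condition_map` data.frame.
#' @export
condition_map <- function(column, enzyme_conc, conc_unit = "mg/mL",
                          substrate = "PCL", temperature = NA_real_,
                          enzyme = "enzyme", replicate = 1L) {
  check_numeric_vec(enzyme_conc, "enzyme_conc", nonneg = TRUE,
                    min_len = length(column))
  if (length(enzyme_conc) != length(column))
    hk_stop_invalid("enzyme_conc", "must have one value per column")
  df <- data.frame(column = as.character(column),
                   enzyme_conc = enzyme_conc, conc_unit = conc_unit,
                   substrate = substrate, temperature = temperature,
                   enzyme = enzyme, replicate = replicate,
                   stringsAsFactors = FALSE)
  df$enzyme_conc_mg_ml <- mapply(convert_conc, df$enzyme_conc, df$conc_unit)
  structure(df, class = c("condition_map", "data.frame"))
}

#' Write turbidity curves to the interchange CSV
#'
#' One `time` column plus one column per curve; curve metadata (and the
#' generating seed, when given) are recorded in '#' header comments. The
#' companion [condition_map()] is returned invisibly and can also be
#' written with [write_condition_map_csv()].
#'
#' @param curves List of [turbidity_curve()] objects sharing a time grid.
#' @param path Output path.
#' @param seed Optional RNG seed to record in the header.
#' @return The [condition_map()] describing the columns, invisibly.
#' @export
write_turbidity_csv <- function(curves, path, seed = NULL) {
  stopifnot(length(curves) >= 1L)
  times <- curves[[1]]$times
  for (cv in curves)
    if (!isTRUE(all.equal(cv$times, times)))
      hk_stop_invalid("curves", "all curves must share the same time grid")
  cols <- vapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    sprintf("%s_%s_T%g_E%g_r%s", cv$enzyme, cv$substrate, cv$temperature,
            cv$enzyme_conc, as.character(cv$replicate))
  }, character(1))
  cols <- make.unique(cols)
  mat <- cbind(time = times,
               do.call(cbind, lapply(curves, function(cv) cv$turbidity)))
  colnames(mat) <- c("time", cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# turbidity interchange CSV; time in min, absorbance at 600 nm", con)
  if (!is.null(seed)) writeLines(sprintf("# rng_seed: %d", as.integer(seed)), con)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    writeLines(sprintf("# column %s: enzyme=%s substrate=%s temperature=%g enzyme_conc=%g mg/mL replicate=%s",
                       cols[i], cv$enzyme, cv$substrate, cv$temperature,
                       cv$enzyme_conc, as.character(cv$replicate)), con)
  }
  utils::write.csv(as.data.frame(mat), con, row.names = FALSE, quote = FALSE)
  invisible(condition_map(column = cols,
                          enzyme_conc = vapply(curves, `[[`, numeric(1), "enzyme_conc"),
                          substrate = vapply(curves, `[[`, character(1), "substrate"),
                          temperature = vapply(curves, `[[`, numeric(1), "temperature"),
                          enzyme = vapply(curves, `[[`, character(1), "enzyme"),
                          replicate = vapply(curves, function(cv) as.integer(cv$replicate),
                                             integer(1))))
}

#' @rdname write_turbidity_csv
#' @param map A [condition_map()].
#' @export
write_condition_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_turbidity_csv
#' @export
read_condition_map_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  for (col in c("column", "enzyme_conc"))
    if (is.null(df[[col]]))
      hk_stop_invalid("path", sprintf("condition map lacks column '%s'", col))
  condition_map(column = df$column, enzyme_conc = df$enzyme_conc,
                conc_unit = df$conc_unit %||% "mg/mL",
                substrate = df$substrate %||% "PCL",
                temperature = df$temperature %||% NA_real_,
                enzyme = df$enzyme %||% "enzyme",
                replicate = df$replicate %||% 1L)
}

#' Read turbidity curves from the interchange CSV
#'
#' The first column must be the time axis (minutes); every column named in
#' the condition map becomes one [turbidity_curve()]. Data columns not in
#' the map are skipped with a warning; map entries without a matching
#' column, blank cells and non-numeric cells are errors that name the
#' offending row and column.
#'
#' @param path CSV path.
#' @param map A [condition_map()].
#' @return A list of [turbidity_curve()] objects (class
#'   `turbidity_curve_set`).
#' @export
read_turbidity_csv <- function(path, map) {
  stopifnot(inherits(map, "condition_map"))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  raw <- utils::read.csv(text = paste(lines, collapse = "\n"),
                         stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (ncol(raw) < 2L)
    hk_stop_invalid("path", "need a time column plus at least one data column")
  if (tolower(names(raw)[1]) != "time")
    hk_stop_invalid("path", sprintf(
      "first column must be 'time' (min); found '%s'", names(raw)[1]))
  check_col <- function(col) {
    vals <- trimws(raw[[col]])
    bad <- which(!nzchar(vals) | is.na(suppressWarnings(as.numeric(vals))))
    if (length(bad))
      hk_stop_invalid("path", sprintf(
        "non-numeric or blank cell at row %d, column '%s'", bad[1], col))
    as.numeric(vals)
  }
  times <- check_col(names(raw)[1])
  data_cols <- names(raw)[-1]
  unmapped <- setdiff(data_cols, map$column)
  if (length(unmapped))
    warning(sprintf("skipping unmapped column(s): %s",
                    paste(unmapped, collapse = ", ")), call. = FALSE)
  missing <- setdiff(map$column, data_cols)
  if (length(missing))
    hk_stop_invalid("map", sprintf(
      "mapped column(s) not present in the file: %s",
      paste(missing, collapse = ", ")))
  curves <- lapply(seq_len(nrow(map)), function(i) {
    turbidity_curve(times = times, turbidity = check_col(map$column[i]),
                    enzyme_conc = map$enzyme_conc_mg_ml[i],
                    substrate = map$substrate[i],
                    temperature = map$temperature[i],
                    replicate = map$replicate[i],
                    enzyme = map$enzyme[i])
  })
  structure(curves, class = "turbidity_curve_set")
}
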