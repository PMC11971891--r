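# Cohort data model: sample records, permissible-limit registry, CSV I/O,
# validation, exceedance classification and per-matrix descriptive summaries.

HG_MATRICES <- c("breastmilk", "blood", "mother_urine", "child_urine", "food")
HG_GROUPS   <- c("mother", "infant", "household")
HG_UNITS    <- c("ug_per_L", "ug_per_kg")

HG_COLUMNS <- c("subject_id", "group", "matrix", "value", "unit",
                "latitude", "longitude", "linked_mother_id",
                "linked_household_id")

#' Canonical unit for a sample matrix
#'
#' Fluids (breastmilk, blood, urine) are measured in micrograms per litre,
#' food (wheat) in micrograms per kilogram. No silent conversion is ever
#' performed: records must carry the canonical unit of their matrix.
#'
#' @param matrix Character vector of matrix labels.
#' @return Character vector of unit labels (`"ug_per_L"` or `"ug_per_kg"`).
#' @export
matrix_unit <- function(matrix) {
  ifelse(matrix == "food", "ug_per_kg", "ug_per_L")
}

hg_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "hg_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Permissible-limit registry
#'
#' Concentration thresholds per matrix above which a sample is classified as
#' exceeding. Defaults are the WHO-derived limits used throughout the
#' package: breastmilk 1.7 ug/L, blood 20 ug/L, urine (mother and child)
#' 10 ug/L, food 100 ug/kg (WHO/FAO). Mother and child urine share the same
#' numeric limit but remain distinct matrices because results are reported
#' separately for the two groups.
#'
#' @param ... Named overrides, e.g. `breastmilk = 2.0`. Names must be matrix
#'   labels; values positive numbers in the matrix's canonical unit.
#' @return A data.frame with columns `matrix`, `limit`, `unit`,
#'   `source_label`, one row per matrix, of class `hg_limits`.
#' @export
#' @examples
#' default_limits()
#' default_limits(breastmilk = 2.0)
default_limits <- function(...) {
  reg <- data.frame(
    matrix = HG_MATRICES,
    limit  = c(1.7, 20, 10, 10, 100),
    unit   = matrix_unit(HG_MATRICES),
    source_label = c("WHO breastmilk", "WHO blood", "WHO urine",
                     "WHO urine", "WHO/FAO food"),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), HG_MATRICES)
    if (length(bad))
      hg_error(paste0("unknown matrix in limit override: ",
                      paste(bad, collapse = ", ")), "hg_config_error")
    for (m in names(over)) {
      v <- over[[m]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
        hg_error(sprintf("limit for '%s' must be a single positive number", m),
                 "hg_config_error")
      reg$limit[reg$matrix == m] <- v
      reg$source_label[reg$matrix == m] <- "user override"
    }
  }
  class(reg) <- c("hg_limits", "data.frame")
  reg
}

#' Read permissible-limit overrides from a YAML file
#'
#' The file maps matrix labels to positive numeric limits; unlisted matrices
#' keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `hg_limits` registry (see [default_limits()]).
#' @export
limits_from_yaml <- function(path) {
  if (!file.exists(path))
    hg_error(paste0("limit file not found: ", path), "hg_io_error")
  over <- yaml::read_yaml(path)
  do.call(default_limits, over)
}

# Validate a record data.frame against the cohort invariants. Returns the
# frame (with normalised column set) or raises a classed validation error
# naming the offending rows. `lines` maps rows to source line numbers for
# error messages (CSV line numbers when called from read_cohort).
validate_records <- function(df, lines = seq_len(nrow(df)) + 1L) {
  for (col in HG_COLUMNS)
    if (is.null(df[[col]])) df[[col]] <- rep(NA, nrow(df))
  df <- df[HG_COLUMNS]
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  df$matrix <- as.character(df$matrix)
  df$unit <- as.character(df$unit)
  df$value <- as.numeric(df$value)
  df$latitude <- as.numeric(df$latitude)
  df$longitude <- as.numeric(df$longitude)
  df$linked_mother_id <- as.character(df$linked_mother_id)
  df$linked_household_id <- as.character(df$linked_household_id)

  cite <- function(rows) paste0("line(s) ", paste(lines[rows], collapse = ", "))
  bad <- which(!df$matrix %in% HG_MATRICES)
  if (length(bad))
    hg_error(sprintf("unknown matrix label '%s' (%s)",
                     df$matrix[bad[1]], cite(bad)), "hg_validation_error")
  bad <- which(!df$group %in% HG_GROUPS)
  if (length(bad))
    hg_error(sprintf("unknown group label '%s' (%s)",
                     df$group[bad[1]], cite(bad)), "hg_validation_error")
  bad <- which(df$value < 0)
  if (length(bad))
    hg_error(sprintf("negative concentration %s (%s)",
                     df$value[bad[1]], cite(bad)), "hg_validation_error")
  bad <- which(df$unit != matrix_unit(df$matrix))
  if (length(bad))
    hg_error(sprintf("unit '%s' does not match matrix '%s' (%s)",
                     df$unit[bad[1]], df$matrix[bad[1]], cite(bad)),
             "hg_validation_error")
  bad <- which(!is.na(df$latitude) & (df$latitude < -90 | df$latitude > 90))
  if (length(bad))
    hg_error(sprintf("latitude out of range (%s)", cite(bad)),
             "hg_validation_error")
  bad <- which(!is.na(df$longitude) & (df$longitude < -180 | df$longitude > 180))
  if (length(bad))
    hg_error(sprintf("longitude out of range (%s)", cite(bad)),
             "hg_validation_error")
  key <- paste(df$subject_id, df$matrix)
  if (anyDuplicated(key))
    hg_error(sprintf("duplicate subject_id x matrix: %s",
                     key[duplicated(key)][1]), "hg_validation_error")
  rownames(df) <- NULL
  df
}

#' Construct a validated cohort dataset
#'
#' A cohort is an ordered collection of sample records, one measured mercury
#' concentration each: subject id, group (`mother`, `infant`, `household`),
#' matrix, non-negative value in the matrix's canonical unit, optional
#' WGS84 coordinates and mother/household linkage ids. `subject_id` x
#' `matrix` must be unique.
#'
#' @param records A data.frame with (a subset of) columns `subject_id`,
#'   `group`, `matrix`, `value`, `unit`, `latitude`, `longitude`,
#'   `linked_mother_id`, `linked_household_id`. A missing `unit` column is
#'   filled with each matrix's canonical unit.
#' @param provenance Free-text note on where the records came from (source
#'   file or generator seed).
#' @param report Optional validation report list (as produced by
#'   [read_cohort()]).
#' @return An object of class `hg_cohort`.
#' @export
as_cohort <- function(records, provenance = "in-memory", report = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$unit) && !is.null(records$matrix))
    records$unit <- matrix_unit(as.character(records$matrix))
  records <- validate_records(records)
  structure(
    list(records = records,
         provenance = provenance,
         report = report %||% list(n_dropped = 0L, dropped_lines = integer())),
    class = "hg_cohort"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hg_cohort <- function(x, ...) {
  cat("<hg_cohort> ", nrow(x$records), " records (", x$provenance, ")\n",
      sep = "")
  print(table(x$records$matrix))
  invisible(x)
}

#' Number of records per matrix
#' @param ds An `hg_cohort`.
#' @return Named integer vector over the matrices present.
#' @export
matrix_counts <- function(ds) {
  stopifnot(inherits(ds, "hg_cohort"))
  tab <- table(ds$records$matrix)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a cohort from a CSV file
#'
#' Comma-separated, UTF-8, header row required, decimal point only. Rows
#' with a missing concentration are dropped and counted in the validation
#' report; structurally invalid rows (unknown matrix, negative value,
#' mismatched unit) abort with a validation error citing the CSV line.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(subject_id = "ID")`.
#' @return An `hg_cohort`; its `report` element lists `n_dropped` and
#'   `dropped_lines` (1-based file line numbers, header = line 1).
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path))
    hg_error(paste0("cannot read cohort file: ", path), "hg_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df))
        hg_error(sprintf("schema column '%s' not in file", schema[[canon]]),
                 "hg_validation_error")
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  required <- c("subject_id", "group", "matrix", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    hg_error(paste0("missing required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "hg_validation_error")
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  blank <- is.na(df$value) | trimws(df$value) == ""
  report <- list(n_dropped = sum(blank), dropped_lines = lines[blank])
  df <- df[!blank, , drop = FALSE]
  lines <- lines[!blank]
  suppressWarnings(val <- as.numeric(df$value))
  bad <- which(is.na(val))
  if (length(bad))
    hg_error(sprintf("non-numeric value '%s' (line %d)",
                     df$value[bad[1]], lines[bad[1]]), "hg_validation_error")
  df$value <- val
  if (is.null(df$unit) || all(trimws(df$unit) == ""))
    df$unit <- matrix_unit(df$matrix)
  for (col in c("latitude", "longitude"))
    if (!is.null(df[[col]])) {
      df[[col]][trimws(df[[col]]) == ""] <- NA
      df[[col]] <- as.numeric(df[[col]])
    }
  for (col in c("linked_mother_id", "linked_household_id"))
    if (!is.null(df[[col]])) df[[col]][trimws(df[[col]]) == ""] <- NA
  records <- validate_records(df, lines)
  as_cohort_checked(records, provenance = path, report = report)
}

# internal: records already validated
as_cohort_checked <- function(records, provenance, report) {
  structure(list(records = records, provenance = provenance,
                 report = report),
            class = "hg_cohort")
}

#' Write a cohort to CSV
#'
#' The canonical columns are written in fixed order; numeric fields are
#' serialised with 17 significant digits so that [read_cohort()] round-trips
#' every field exactly (coordinates well beyond the 6-decimal contract).
#'
#' @param ds An `hg_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ds, path) {
  stopifnot(inherits(ds, "hg_cohort"))
  df <- ds$records
  for (col in c("value", "latitude", "longitude")) {
    out <- ifelse(is.na(df[[col]]), "",
                  formatC(df[[col]], format = "g", digits = 17))
    df[[col]] <- out
  }
  for (col in names(df)) df[[col]][is.na(df[[col]])] <- ""
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) hg_error(paste0("cannot write cohort file: ", path), "hg_io_error")
  invisible(path)
}

# nearest-integer rounding, ties away from zero (the convention behind the
# reported integer exceedance percentages)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Classify records against permissible limits
#'
#' A record exceeds iff `value > limit` (strict: a value exactly equal to
#' the limit is *not* exceeding, since the permissible ranges are stated as
#' strictly below the limit). Set `strict = FALSE` to flag `value >= limit`
#' instead.
#'
#' @param ds An `hg_cohort`.
#' @param limits An `hg_limits` registry; defaults to [default_limits()].
#' @param strict Logical; exceed on `>` (default) or `>=`.
#' @return A list with `records` (the record frame plus logical `exceeds`
#'   and the applied `limit`) and `summary` (one [summarize_matrix()] row
#'   per matrix present, as a data.frame).
#' @export
classify_exceedance <- function(ds, limits = default_limits(), strict = TRUE) {
  stopifnot(inherits(ds, "hg_cohort"))
  df <- ds$records
  present <- unique(df$matrix)
  missing_lim <- setdiff(present, limits$matrix)
  if (length(missing_lim))
    hg_error(paste0("no permissible limit for matrix: ",
                    paste(missing_lim, collapse = ", ")), "hg_config_error")
  idx <- match(df$matrix, limits$matrix)
  if (any(df$unit != limits$unit[idx]))
    hg_error("record unit does not match limit unit", "hg_config_error")
  df$limit <- limits$limit[idx]
  df$exceeds <- if (strict) df$value > df$limit else df$value >= df$limit
  summ <- do.call(rbind, lapply(sort(present), function(m)
    summarize_matrix(ds, m, limits = limits, strict = strict)))
  list(records = df, summary = summ)
}

#' Descriptive summary of one matrix
#'
#' Counts below/above the permissible limit, the maximum, arithmetic mean,
#' median and geometric mean (computed on strictly positive values, with
#' the zero count reported separately), and the exceedance percentage both
#' exact and rounded to the nearest integer (ties away from zero).
#'
#' @param ds An `hg_cohort`.
#' @param matrix One matrix label.
#' @param limits An `hg_limits` registry.
#' @param strict Boundary semantics as in [classify_exceedance()].
#' @return A one-row data.frame: `matrix`, `n_total`, `n_below_limit`,
#'   `n_above_limit`, `max_value`, `mean`, `median`, `geometric_mean`,
#'   `n_zeros`, `exceedance_percent_exact`, `exceedance_percent`. For an
#'   empty matrix `n_total` is 0 and the statistics are `NA` (an explicit
#'   empty-summary signal, not an error).
#' @export
summarize_matrix <- function(ds, matrix, limits = default_limits(),
                             strict = TRUE) {
  stopifnot(inherits(ds, "hg_cohort"), matrix %in% HG_MATRICES)
  x <- ds$records$value[ds$records$matrix == matrix]
  lim <- limits$limit[limits$matrix == matrix]
  if (length(lim) != 1L)
    hg_error(paste0("no permissible limit for matrix: ", matrix),
             "hg_config_error")
  if (length(x) == 0L) {
    return(data.frame(matrix = matrix, n_total = 0L, n_below_limit = 0L,
                      n_above_limit = 0L, max_value = NA_real_,
                      mean = NA_real_, median = NA_real_,
                      geometric_mean = NA_real_, n_zeros = 0L,
                      exceedance_percent_exact = NA_real_,
                      exceedance_percent = NA_real_,
                      stringsAsFactors = FALSE))
  }
  above <- if (strict) sum(x > lim) else sum(x >= lim)
  pos <- x[x > 0]
  gm <- if (length(pos)) exp(mean(log(pos))) else NA_real_
  pct <- 100 * above / length(x)
  data.frame(matrix = matrix, n_total = length(x),
             n_below_limit = length(x) - above, n_above_limit = above,
             max_value = max(x), mean = mean(x), median = stats::median(x),
             geometric_mean = gm, n_zeros = sum(x == 0),
             exceedance_percent_exact = pct,
             exceedance_percent = round_half_away(pct),
             stringsAsFactors = FALSE)
}
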