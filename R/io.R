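#' Build a monitoring tibble in code
#'
#' Convenience constructor for one facility x parameter series, mostly used
#' by the synthetic generator and in tests. Values reported below a
#' detection limit are flagged as censored; by convention the stored `value`
#' equals the detection limit.
#'
#' @param facility_id Facility label.
#' @param parameter Parameter code (see [cpi_parameters()]).
#' @param values Numeric measurements.
#' @param dates Measurement dates; defaults to consecutive days.
#' @param censored Logical, recycled; `TRUE` marks below-detection records.
#' @param detection_limit Numeric, recycled; required where `censored`.
#' @return A monitoring tibble (columns `facility_id`, `parameter`, `date`,
#'   `value`, `censored`, `detection_limit`).
#' @export
monitoring_series <- function(facility_id, parameter, values,
                              dates = NULL,
                              censored = FALSE,
                              detection_limit = NA_real_) {
  n <- length(values)
  if (n == 0) stop("a monitoring series needs at least one measurement", call. = FALSE)
  if (is.null(dates)) dates <- as.Date("2020-01-01") + seq_len(n) - 1
  if (is.unsorted(dates)) stop("dates must be non-decreasing", call. = FALSE)
  censored <- rep_len(censored, n)
  detection_limit <- rep_len(as.numeric(detection_limit), n)
  if (any(censored & is.na(detection_limit)))
    stop("censored measurements need a detection limit", call. = FALSE)
  values <- as.numeric(values)
  values[censored] <- detection_limit[censored]
  tibble::tibble(
    facility_id = facility_id, parameter = parameter,
    date = as.Date(dates), value = values,
    censored = censored, detection_limit = detection_limit
  )
}

#' Read long-format effluent monitoring data
#'
#' Expects a CSV with columns `facility_id,date,parameter,value,unit`
#' (ISO-8601 dates). Values written as `"<x"` are parsed as censored
#' below-detection measurements with detection limit `x` — the convention
#' used for coliform counts reported as `<1` MPN/100mL.
#'
#' @param path CSV file.
#' @param parameters Parameter definitions used to validate codes and
#'   units; defaults to [cpi_parameters()].
#' @return A monitoring tibble, sorted by facility, parameter, date.
#' @export
read_monitoring_csv <- function(path, parameters = cpi_parameters()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("facility_id", "date", "parameter", "value", "unit")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("monitoring CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0) stop("no records in ", path, call. = FALSE)

  unknown <- setdiff(unique(raw$parameter), parameters$code)
  if (length(unknown))
    stop("unknown parameter code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  pdef <- parameters[match(raw$parameter, parameters$code), ]
  bad_unit <- which(raw$unit != pdef$unit)
  if (length(bad_unit))
    stop("unit mismatch at row ", bad_unit[1], ": parameter ",
         raw$parameter[bad_unit[1]], " expects '", pdef$unit[bad_unit[1]],
         "', got '", raw$unit[bad_unit[1]], "'", call. = FALSE)

  val <- trimws(raw$value)
  censored <- startsWith(val, "<")
  num_str <- ifelse(censored, substring(val, 2), val)
  num <- suppressWarnings(as.numeric(num_str))
  bad <- which(is.na(num))
  if (length(bad))
    stop("non-numeric value '", raw$value[bad[1]], "' at row ", bad[1],
         call. = FALSE)

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad_date <- which(is.na(date))
  if (length(bad_date))
    stop("unparseable ISO-8601 date '", raw$date[bad_date[1]], "' at row ",
         bad_date[1], call. = FALSE)

  out <- tibble::tibble(
    facility_id = raw$facility_id, parameter = raw$parameter,
    date = date, value = num,
    censored = censored,
    detection_limit = ifelse(censored, num, NA_real_)
  )
  dplyr::arrange(out, .data$facility_id, .data$parameter, .data$date)
}

#' Write monitoring data back to the long CSV format
#'
#' Censored measurements are serialized as `"<limit"`, so a write/read
#' round trip preserves values, censor flags and dates exactly.
#'
#' @param data Monitoring tibble.
#' @param path Output CSV path.
#' @param parameters Parameter definitions supplying the `unit` column.
#' @return `path`, invisibly.
#' @export
write_monitoring_csv <- function(data, path, parameters = cpi_parameters()) {
  unit <- parameters$unit[match(data$parameter, parameters$code)]
  value_chr <- ifelse(data$censored,
                      paste0("<", format(data$detection_limit, trim = TRUE,
                                         scientific = FALSE)),
                      format(data$value, trim = TRUE, scientific = FALSE,
                             digits = 15))
  out <- tibble::tibble(
    facility_id = data$facility_id,
    date = format(data$date, "%Y-%m-%d"),
    parameter = data$parameter,
    value = value_chr, unit = unit
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read reuse-scenario standards from a YAML configuration
#'
#' The configuration declares, per scenario, a description and one
#' objective per parameter (`bound: upper|lower|range|absent` with `low`
#' and/or `high` limits). The configuration bundled with the package
#' (`system.file("extdata", "standards.yaml", package = "aquacpi")`)
#' encodes the default standards for the four reuse scenarios S1-S4.
#'
#' @param path YAML file; defaults to the bundled standards.
#' @return Named list of [scenario_standards()] objects.
#' @export
#' @examples
#' std <- read_standards_config()
#' std$S1$objectives$BOD5
read_standards_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "standards.yaml", package = "aquacpi")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios) || !length(cfg$scenarios))
    stop("standards config declares no scenarios", call. = FALSE)
  out <- lapply(names(cfg$scenarios), function(sid) {
    sc <- cfg$scenarios[[sid]]
    objs <- lapply(names(sc$objectives), function(code) {
      o <- sc$objectives[[code]]
      if (is.null(o$bound))
        stop("objective for ", code, " in ", sid, " lacks a bound type",
             call. = FALSE)
      if (o$bound != "absent" && is.null(o$low) && is.null(o$high))
        stop("objective for ", code, " in ", sid,
             " has no limits but bound type is not 'absent'", call. = FALSE)
      objective(o$bound, low = o$low, high = o$high)
    })
    names(objs) <- names(sc$objectives)
    scenario_standards(sid, objs, description = sc$description %||% "")
  })
  names(out) <- names(cfg$scenarios)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an assessment report
#'
#' Serializes the result table of [assess()] to JSON, CSV, or a Markdown
#' table. JSON and CSV carry identical numeric values; the Markdown writer
#' rounds for display.
#'
#' @param results Assessment tibble from [assess()].
#' @param path Output file.
#' @param format `"json"`, `"csv"`, or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  if (is.null(results) || nrow(results) == 0)
    stop("no results to report", call. = FALSE)
  flat <- results
  if ("actions" %in% names(flat))
    flat$actions <- vapply(flat$actions, paste, character(1), collapse = " | ")
  switch(format,
    json = jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", na = "null"),
    csv = readr::write_csv(flat, path, progress = FALSE),
    markdown = {
      num <- vapply(flat, is.numeric, logical(1))
      flat[num] <- lapply(flat[num], function(x) round(x, 2))
      cells <- vapply(flat, function(x) format(x, trim = TRUE), character(nrow(flat)))
      cells <- matrix(as.character(cells), nrow = nrow(flat))
      lines <- c(
        paste0("| ", paste(names(flat), collapse = " | "), " |"),
        paste0("|", paste(rep("---", ncol(flat)), collapse = "|"), "|"),
        apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
      )
      writeLines(lines, path)
    }
  )
  invisible(path)
}
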