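#' Does a measurement violate an objective?
#'
#' Direction-aware compliance test. Boundary equality is compliant by
#' default: a value exactly at a limit passes (`strict = TRUE` flips this
#' for users whose regulator treats limits as exclusive). For `absent`
#' objectives any quantified presence fails; censored below-detection
#' records, and a quantified zero, comply.
#'
#' @param value Numeric measurement(s).
#' @param objective A [objective()].
#' @param censored Logical, recycled: below-detection flag per value.
#' @param strict If `TRUE`, equality at a limit counts as a violation.
#' @return Logical vector.
#' @export
#' @examples
#' is_violation(10, objective("upper", high = 10))            # FALSE
#' is_violation(5, objective("range", low = 6, high = 8.4))   # TRUE
#' is_violation(1, objective("absent"), censored = TRUE)      # FALSE
is_violation <- function(value, objective, censored = FALSE, strict = FALSE) {
  stopifnot(inherits(objective, "cpi_objective"))
  censored <- rep_len(censored, length(value))
  gt <- if (strict) `>=` else `>`
  lt <- if (strict) `<=` else `<`
  out <- switch(objective$bound_type,
    upper  = gt(value, objective$high),
    lower  = lt(value, objective$low),
    range  = gt(value, objective$high) | lt(value, objective$low),
    absent = !censored & value > 0
  )
  # a censored record can never exceed an upper limit below the DL by more
  # than its reported surrogate value; evaluate it at the detection limit,
  # which is what `value` stores by convention
  out
}

#' Summarize compliance of a series against one objective
#'
#' Counts failed tests and retains the failed values (used later for the
#' amplitude excursions of the CWQI).
#'
#' @param values Numeric measurements.
#' @param objective A [objective()].
#' @param censored Logical, recycled.
#' @param strict Passed to [is_violation()].
#' @return A `cpi_compliance` list: `n_tests`, `n_failed`, `failed_values`,
#'   `objective`.
#' @export
summarize_compliance <- function(values, objective, censored = FALSE,
                                 strict = FALSE) {
  if (length(values) == 0) stop("empty series", call. = FALSE)
  bad <- is_violation(values, objective, censored = censored, strict = strict)
  structure(list(
    n_tests = length(values),
    n_failed = sum(bad),
    failed_values = values[bad],
    objective = objective
  ), class = "cpi_compliance")
}

#' Non-exceedance probability of meeting an objective
#'
#' Rank-based (plotting-position) probability that a parameter meets its
#' objective. The objective value is inserted into the severity-sorted
#' sample and takes rank `m = 1 + (number of violations)`; the exceedance
#' probability is the Weibull plotting position `Pe = 100 m / (n + 1)` and
#' the non-exceedance probability is `P = 100 - Pe`, clamped to
#' `[0.01, 99.99]` percent. A series that never fails therefore scores
#' `100 n/(n+1)` — approaching but never reaching 100 — while a series that
#' always fails hits the 0.01 floor.
#'
#' Microbiological `absent` objectives where every record is a censored
#' non-detect short-circuit to `P = 99.99` regardless of `n`.
#'
#' @inheritParams summarize_compliance
#' @param clamp Two-element percent band; defaults to `c(0.01, 99.99)`.
#' @return Percent scalar in `clamp`.
#' @export
#' @examples
#' nonexceedance_probability(c(1, 2, 3, 4), objective("upper", high = 10)) # 80
nonexceedance_probability <- function(values, objective, censored = FALSE,
                                      strict = FALSE,
                                      clamp = c(0.01, 99.99)) {
  if (length(values) == 0) stop("empty series", call. = FALSE)
  censored <- rep_len(censored, length(values))
  if (objective$bound_type == "absent" && all(censored))
    return(clamp[2])
  n <- length(values)
  m <- 1 + sum(is_violation(values, objective, censored = censored,
                            strict = strict))
  pe <- 100 * m / (n + 1)
  p <- 100 - pe
  min(max(p, clamp[1]), clamp[2])
}

#' Non-exceedance probability table for a monitoring dataset
#'
#' One row per facility x parameter: sample size `n`, number of failed
#' tests, rank `m`, exceedance probability `Pe` and non-exceedance
#' probability `P` against the objectives of one reuse scenario.
#'
#' @param data Monitoring tibble (see [read_monitoring_csv()]).
#' @param standards A [scenario_standards()] object.
#' @param strict,clamp Passed through to [nonexceedance_probability()].
#' @return A `cpi_ptable` tibble with attribute `scenario_id`.
#' @export
build_p_table <- function(data, standards, strict = FALSE,
                          clamp = c(0.01, 99.99)) {
  stopifnot(inherits(standards, "cpi_standards"))
  missing_obj <- setdiff(unique(data$parameter), names(standards$objectives))
  if (length(missing_obj))
    stop("no objective for parameter(s) ", paste(missing_obj, collapse = ", "),
         " in scenario ", standards$scenario_id, call. = FALSE)
  out <- data |>
    dplyr::group_by(.data$facility_id, .data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_failed = sum(is_violation(.data$value,
                                  standards$objectives[[.data$parameter[1]]],
                                  censored = .data$censored, strict = strict)),
      P = nonexceedance_probability(.data$value,
                                    standards$objectives[[.data$parameter[1]]],
                                    censored = .data$censored, strict = strict,
                                    clamp = clamp),
      .groups = "drop"
    ) |>
    dplyr::mutate(m = .data$n_failed + 1, Pe = 100 - .data$P) |>
    dplyr::select("facility_id", "parameter", "n", "n_failed", "m", "Pe", "P")
  new_ptable(out, standards$scenario_id)
}

#' Construct a probability table from precomputed values
#'
#' Wraps already-known non-exceedance probabilities (for example the
#' bundled reference table, see [load_reference_table()]) in the container
#' the grey index expects. Bookkeeping columns that depend on raw data
#' (`n`, `m`, `Pe`) are filled where derivable.
#'
#' @param df Data frame with columns `facility_id`, `parameter`, `P`.
#' @param scenario_id Scenario label.
#' @return A `cpi_ptable` tibble.
#' @export
as_p_table <- function(df, scenario_id) {
  stopifnot(all(c("facility_id", "parameter", "P") %in% names(df)))
  if (any(df$P < 0 | df$P > 100)) stop("P must be a percent", call. = FALSE)
  out <- tibble::tibble(
    facility_id = df$facility_id, parameter = df$parameter,
    n = if ("n" %in% names(df)) df$n else NA_integer_,
    n_failed = if ("n_failed" %in% names(df)) df$n_failed else NA_integer_,
    m = if ("m" %in% names(df)) df$m else NA_integer_,
    Pe = 100 - df$P, P = df$P
  )
  new_ptable(out, scenario_id)
}

new_ptable <- function(df, scenario_id) {
  structure(df, scenario_id = scenario_id,
            class = c("cpi_ptable", class(tibble::tibble())))
}

#' @export
print.cpi_ptable <- function(x, ...) {
  cat("Non-exceedance probabilities, scenario",
      attr(x, "scenario_id") %||% "?", "\n")
  NextMethod()
}
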