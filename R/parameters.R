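#' Default effluent water quality parameter set
#'
#' The eleven parameters routinely monitored at tertiary wastewater
#' treatment plants (extended aeration, sand filtration, chlorination):
#' two physical, seven chemical, and two biological.
#'
#' @return A tibble with columns `code`, `name`, `unit`, `group`.
#'   `group` is one of `"physical"`, `"chemical"`, `"biological"`;
#'   biological parameters carry a count-per-volume unit (MPN/100mL).
#' @export
#' @examples
#' cpi_parameters()
cpi_parameters <- function() {
  tibble::tribble(
    ~code,    ~name,                       ~unit,       ~group,
    "TDS",    "Total dissolved solids",    "mg/L",      "physical",
    "TSS",    "Total suspended solids",    "mg/L",      "physical",
    "pH",     "pH",                        "-",         "chemical",
    "BOD5",   "Biochemical oxygen demand", "mg/L",      "chemical",
    "COD",    "Chemical oxygen demand",    "mg/L",      "chemical",
    "NH3-N",  "Ammonia nitrogen",          "mg/L",      "chemical",
    "NO3-N",  "Nitrate nitrogen",          "mg/L",      "chemical",
    "PO4-P",  "Phosphates",                "mg/L",      "chemical",
    "Cl2",    "Residual chlorine",         "mg/L",      "chemical",
    "TC",     "Total coliforms",           "MPN/100mL", "biological",
    "FC",     "Fecal coliforms",           "MPN/100mL", "biological"
  )
}

#' Define an effluent quality objective for one parameter
#'
#' An objective is the standard (guideline limit) a parameter must meet for
#' a given reuse scenario. Four bound types are supported: `upper` (value
#' must not exceed `high`), `lower` (value must not fall below `low`),
#' `range` (value must stay within `[low, high]`, e.g. pH or residual
#' chlorine), and `absent` (the target is complete absence, used for fecal
#' indicators under unrestricted-contact scenarios).
#'
#' Boundary equality is compliant: a value exactly at a limit passes.
#'
#' @param bound_type One of `"upper"`, `"lower"`, `"range"`, `"absent"`.
#' @param low,high Numeric limits; which must be supplied depends on
#'   `bound_type` (`upper` needs `high` only, `range` needs `low < high`,
#'   `absent` takes neither).
#' @return An object of class `cpi_objective`.
#' @export
#' @examples
#' objective("upper", high = 40)           # BOD5 for restricted irrigation
#' objective("range", low = 0.2, high = 0.5)  # residual chlorine
#' objective("absent")                     # fecal coliforms, strictest reuse
objective <- function(bound_type = c("upper", "lower", "range", "absent"),
                      low = NULL, high = NULL) {
  bound_type <- match.arg(bound_type)
  low <- if (is.null(low)) NA_real_ else as.numeric(low)
  high <- if (is.null(high)) NA_real_ else as.numeric(high)
  switch(bound_type,
    upper = {
      if (is.na(high)) stop("'upper' objective requires `high`", call. = FALSE)
      if (!is.na(low)) stop("'upper' objective must not set `low`", call. = FALSE)
    },
    lower = {
      if (is.na(low)) stop("'lower' objective requires `low`", call. = FALSE)
      if (!is.na(high)) stop("'lower' objective must not set `high`", call. = FALSE)
    },
    range = {
      if (is.na(low) || is.na(high))
        stop("'range' objective requires both `low` and `high`", call. = FALSE)
      if (low >= high)
        stop("'range' objective requires low < high (got ", low, " >= ", high, ")",
             call. = FALSE)
    },
    absent = {
      if (!is.na(low) || !is.na(high))
        stop("'absent' objective takes no numeric limits", call. = FALSE)
    }
  )
  structure(list(bound_type = bound_type, low = low, high = high),
            class = "cpi_objective")
}

#' @export
print.cpi_objective <- function(x, ...) {
  lbl <- switch(x$bound_type,
    upper  = paste0("<= ", x$high),
    lower  = paste0(">= ", x$low),
    range  = paste0("[", x$low, ", ", x$high, "]"),
    absent = "absent (no quantified presence)"
  )
  cat("<objective> ", lbl, "\n", sep = "")
  invisible(x)
}

#' Bundle per-parameter objectives into a reuse-scenario standard
#'
#' @param scenario_id Scenario label, e.g. `"S1"`.
#' @param objectives Named list of [objective()] items, names are parameter
#'   codes.
#' @param description Free-text description of the reuse application.
#' @return An object of class `cpi_standards`.
#' @export
scenario_standards <- function(scenario_id, objectives, description = "") {
  stopifnot(is.character(scenario_id), length(scenario_id) == 1)
  if (length(objectives) == 0 || is.null(names(objectives)) ||
      any(!nzchar(names(objectives))))
    stop("`objectives` must be a non-empty named list", call. = FALSE)
  ok <- vapply(objectives, inherits, logical(1), what = "cpi_objective")
  if (!all(ok))
    stop("all objectives must be created with objective()", call. = FALSE)
  structure(list(scenario_id = scenario_id,
                 description = description,
                 objectives = objectives),
            class = "cpi_standards")
}

#' @export
print.cpi_standards <- function(x, ...) {
  cat("<scenario standards> ", x$scenario_id,
      if (nzchar(x$description)) paste0(": ", x$description), "\n", sep = "")
  for (code in names(x$objectives)) {
    o <- x$objectives[[code]]
    lbl <- switch(o$bound_type,
      upper = paste0("<= ", o$high), lower = paste0(">= ", o$low),
      range = paste0("[", o$low, ", ", o$high, "]"), absent = "absent")
    cat(format(code, width = 7), lbl, "\n")
  }
  invisible(x)
}
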