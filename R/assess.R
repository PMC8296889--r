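#' Improvement-action rules per reuse scenario
#'
#' The static lookup of proposed improvement actions for each continuous
#' performance improvement (CPI) scenario: process control and chlorination
#' attention for the existing irrigation scenarios, membrane bioreactor
#' integration for nutrient removal from cycle 1 onward, and a reverse
#' osmosis upgrade for dissolved solids removal in cycle 2.
#'
#' @return Tibble with `scenario` and a list-column `actions`.
#' @export
action_rules <- function() {
  tibble::tibble(
    scenario = c("S1", "S2", "S3", "S4"),
    actions = list(
      c("Careful monitoring and process control.",
        "Attention is required for controlling residual chlorine."),
      c("Careful monitoring and process control.",
        "Attention is required for controlling residual chlorine."),
      c("Careful monitoring and process control.",
        "Improve nutrients removal by integrating the existing system with a membrane bioreactor (MBR) process."),
      c("Careful monitoring and process control.",
        "Improve nutrients removal by integrating the existing system with a membrane bioreactor (MBR) process.",
        "Upgrade tertiary treatment by adding a reverse osmosis process for the removal of total dissolved solids (TDS) and dissolved organics.")
    )
  )
}

#' Recommended actions for one facility result
#'
#' Always includes the scenario's improvement actions, then appends
#' benchmark-position advice: facilities below the benchmark need major
#' improvement to catch up with the better performers; facilities above it
#' in the Excellent band primarily need to maintain performance, and
#' otherwise minor improvements (monitoring frequency, proactive
#' maintenance) can lift them into the Excellent zone.
#'
#' @param scenario_id Scenario label.
#' @param category Performance category of the facility's index.
#' @param gap Index minus benchmark.
#' @param rules Action rule table, default [action_rules()].
#' @return Character vector of recommendations.
#' @export
recommend <- function(scenario_id, category, gap, rules = action_rules()) {
  base <- rules$actions[rules$scenario == scenario_id]
  if (length(base) == 0)
    stop("no action rules for scenario ", scenario_id, call. = FALSE)
  advice <- if (!is.na(gap) && gap < 0) {
    "Below benchmark: major improvement needed to match better-performing facilities and stricter future standards."
  } else if (identical(category, "Excellent")) {
    "Above benchmark, excellent performance: maintain performance."
  } else {
    "Above benchmark: minor improvements (monitoring frequency, proactive maintenance) can lift performance to the excellent zone."
  }
  c(base[[1]], advice)
}

#' Assess facilities across reuse scenarios
#'
#' End-to-end orchestration: for each scenario, builds the non-exceedance
#' probability table and the grey relational index (GWQI), computes the
#' modified CWQI with its factors and sub-indices, derives the
#' cross-facility benchmark (arithmetic mean per scenario and index, or a
#' flow-weighted mean if facility flows are supplied), the performance gap
#' of each facility, and the recommended actions.
#'
#' @param data Monitoring tibble covering one or more facilities.
#' @param standards Named list of [scenario_standards()] (default: the
#'   bundled standards).
#' @param weights Importance weights for the GWQI: either a single data
#'   frame with columns `parameter`, `W` (optionally `scenario`), or a
#'   named list of such per scenario. Default: the bundled reference
#'   weights. Ignored when `"gwqi"` is not among `indices`.
#' @param scenarios Scenario labels to assess.
#' @param indices Any of `"gwqi"`, `"cwqi"`.
#' @param xi Grey distinguishing coefficient.
#' @param excursion_cap,strict,scope_all_parameters Passed to
#'   [ccme_index()] / the compliance layer.
#' @param flow_weights Optional named numeric (facility -> average flow,
#'   m3/day) for a flow-weighted benchmark instead of the plain mean.
#' @param presumed_benchmark Reporting overlay for the target performance
#'   level (default 90, the excellent/very-good boundary region); not used
#'   in gap arithmetic.
#' @param parameters Parameter definitions.
#' @return Tibble, one row per facility x scenario, with index values,
#'   factors, categories, benchmarks, gaps and an `actions` list-column.
#' @export
assess <- function(data,
                   standards = read_standards_config(),
                   weights = NULL,
                   scenarios = names(standards),
                   indices = c("gwqi", "cwqi"),
                   xi = 0.5,
                   excursion_cap = 100,
                   strict = FALSE,
                   scope_all_parameters = FALSE,
                   flow_weights = NULL,
                   presumed_benchmark = 90,
                   parameters = cpi_parameters()) {
  indices <- match.arg(indices, several.ok = TRUE)
  if (inherits(standards, "cpi_standards")) {
    standards <- stats::setNames(list(standards), standards$scenario_id)
  }
  miss <- setdiff(scenarios, names(standards))
  if (length(miss))
    stop("no standards for scenario(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  weight_for <- function(sid) {
    w <- weights
    if (is.null(w)) {
      w <- load_reference_table("weights")
    }
    if (is.list(w) && !is.data.frame(w)) {
      if (is.null(w[[sid]])) stop("no weights for scenario ", sid, call. = FALSE)
      return(tibble::as_tibble(w[[sid]]))
    }
    w <- tibble::as_tibble(w)
    if ("scenario" %in% names(w)) w <- w[w$scenario == sid, ]
    w[, c("parameter", "W")]
  }

  bench <- function(x, facilities) {
    if (is.null(flow_weights)) return(mean(x))
    fw <- flow_weights[facilities]
    if (anyNA(fw)) stop("flow weights missing for some facilities", call. = FALSE)
    sum(x * fw) / sum(fw)
  }

  purrr::map_dfr(scenarios, function(sid) {
    std <- standards[[sid]]
    facs <- sort(unique(data$facility_id))
    res <- tibble::tibble(facility_id = facs, scenario = sid)

    if ("gwqi" %in% indices) {
      pt <- build_p_table(data, std, strict = strict)
      g <- gwqi(pt, weight_for(sid), xi = xi)
      res <- dplyr::left_join(res, g, by = "facility_id")
      gb <- bench(res$gwqi, res$facility_id)
      res$gwqi_benchmark <- gb
      res$gwqi_gap <- res$gwqi - gb
    }
    if ("cwqi" %in% indices) {
      cc <- purrr::map_dfr(facs, function(f) {
        ccme_index(data[data$facility_id == f, ], std,
                   parameters = parameters, excursion_cap = excursion_cap,
                   strict = strict,
                   scope_all_parameters = scope_all_parameters)
      })
      res <- dplyr::left_join(res, dplyr::select(cc, -"scenario"),
                              by = "facility_id")
      cb <- bench(res$cwqi, res$facility_id)
      res$cwqi_benchmark <- cb
      res$cwqi_gap <- res$cwqi - cb
    }
    # category/gap driving the recommendation: the CWQI where computed
    # (the stricter index), otherwise the GWQI
    drive_val <- if ("cwqi" %in% indices) res$cwqi else res$gwqi
    drive_gap <- if ("cwqi" %in% indices) res$cwqi_gap else res$gwqi_gap
    if (!"category" %in% names(res)) res$category <- categorize(drive_val)
    res$presumed_benchmark <- presumed_benchmark
    res$actions <- purrr::map2(res$category, drive_gap,
                               function(cat, gap) recommend(sid, cat, gap))
    res
  })
}
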