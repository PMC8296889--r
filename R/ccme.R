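#' Scope and frequency factors (F1, F2)
#'
#' F1 (scope) is the percentage of parameters that failed their objective
#' at least once during the assessment period; F2 (frequency) is the
#' percentage of individual tests that failed, pooled over all parameters.
#' Both are computed over the physico-chemical parameters only — coliforms,
#' whose target is complete absence, are handled by the separate
#' microbiological sub-index ([wqi_mb()]).
#'
#' @param summaries List of `cpi_compliance` objects
#'   (see [summarize_compliance()]), one per parameter.
#' @return Named list `F1`, `F2` (percent).
#' @export
scope_frequency <- function(summaries) {
  if (length(summaries) == 0) stop("no compliance summaries", call. = FALSE)
  n_failed_param <- sum(vapply(summaries, function(s) s$n_failed > 0, logical(1)))
  total_tests <- sum(vapply(summaries, `[[`, numeric(1), "n_tests"))
  total_failed <- sum(vapply(summaries, `[[`, numeric(1), "n_failed"))
  list(F1 = 100 * n_failed_param / length(summaries),
       F2 = 100 * total_failed / total_tests)
}

#' Amplitude factor (F3) via excursions and nse
#'
#' Each failed test contributes an excursion measuring how far it missed
#' its objective: `value/high - 1` for an exceeded upper limit and
#' `low/value - 1` for an undershot lower limit (range objectives dispatch
#' per violated side). The normalized sum of excursions is
#' `nse = sum(excursions) / (total number of tests)` — all tests, not just
#' the failed ones — and the amplitude is the asymptotic rescaling
#' `F3 = nse / (0.01 nse + 0.01)`, which maps nse = 1 to 50 and approaches
#' 100 as failures grow without bound.
#'
#' A lower-side excursion blows up as the failed value approaches zero
#' (e.g. a residual-chlorine reading of 0 against a 0.2 mg/L floor); each
#' excursion is therefore capped (default 100) to keep nse finite.
#'
#' @param summaries List of `cpi_compliance` objects (physico-chemical).
#' @param excursion_cap Upper cap applied to each individual excursion.
#' @return Named list `excursions` (numeric vector), `nse`, `F3`.
#' @export
amplitude <- function(summaries, excursion_cap = 100) {
  if (length(summaries) == 0) stop("no compliance summaries", call. = FALSE)
  exc <- unlist(lapply(summaries, function(s) {
    if (s$n_failed == 0) return(numeric(0))
    o <- s$objective
    vapply(s$failed_values, function(v) {
      e <- if (!is.na(o$high) && v > o$high) {
        v / o$high - 1
      } else if (!is.na(o$low) && v < o$low) {
        if (v <= 0) Inf else o$low / v - 1
      } else {
        stop("failed value ", v, " has no violated numeric limit", call. = FALSE)
      }
      min(e, excursion_cap)
    }, numeric(1))
  }))
  if (is.null(exc)) exc <- numeric(0)
  total_tests <- sum(vapply(summaries, `[[`, numeric(1), "n_tests"))
  nse <- sum(exc) / total_tests
  list(excursions = exc, nse = nse, F3 = nse / (0.01 * nse + 0.01))
}

#' Physico-chemical CWQI from the three factors
#'
#' `CWQI_PC = 100 - sqrt(F1^2 + F2^2 + F3^2) / 1.732`. The divisor 1.732
#' (sqrt of 3) normalizes the vector norm of the three factors — each of
#' which can reach 100 — so the index spans 0 to 100; small negative
#' residues from the rounded divisor are floored at 0.
#'
#' @param F1,F2,F3 Factors in `[0, 100]`.
#' @return Index value in `[0, 100]`.
#' @export
#' @examples
#' cwqi_pc(0, 0, 0)       # 100
#' cwqi_pc(100, 100, 100) # 0
cwqi_pc <- function(F1, F2, F3) {
  stopifnot(F1 >= 0, F1 <= 100, F2 >= 0, F2 <= 100, F3 >= 0, F3 < 100 + 1e-9)
  max(0, 100 - sqrt(F1^2 + F2^2 + F3^2) / 1.732)
}

#' Microbiological sub-index
#'
#' Pass fraction of the coliform tests:
#' `WQI_MB = 100 * (1 - failed / total)`.
#'
#' @param summaries List of `cpi_compliance` objects for the biological
#'   parameters.
#' @return Percent in `[0, 100]`.
#' @export
wqi_mb <- function(summaries) {
  if (length(summaries) == 0) stop("no microbiological summaries", call. = FALSE)
  total <- sum(vapply(summaries, `[[`, numeric(1), "n_tests"))
  if (total == 0) stop("zero microbiological tests", call. = FALSE)
  failed <- sum(vapply(summaries, `[[`, numeric(1), "n_failed"))
  100 * (1 - failed / total)
}

#' Scenario weighting of the two sub-indices
#'
#' Default weights (W1 for the physico-chemical index, W2 for the
#' microbiological sub-index) grow the microbiological share as reuse
#' scenarios involve more human contact: S1 (0.9, 0.1), S2 (0.8, 0.2),
#' S3 and S4 (0.7, 0.3).
#'
#' @param scenario_id Scenario label.
#' @param table Optional override: data frame with `scenario`, `W1`, `W2`.
#' @return Named list `W1`, `W2` with `W1 + W2 = 1`.
#' @export
ccme_weights <- function(scenario_id, table = NULL) {
  if (is.null(table)) table <- load_reference_table("ccme_weights")
  row <- table[table$scenario == scenario_id, ]
  if (nrow(row) != 1)
    stop("no sub-index weights for scenario ", scenario_id, call. = FALSE)
  if (abs(row$W1 + row$W2 - 1) > 1e-9)
    stop("sub-index weights must sum to 1", call. = FALSE)
  list(W1 = row$W1, W2 = row$W2)
}

#' Modified CWQI: weighted combination of the two sub-indices
#'
#' `modified CWQI = W1 * CWQI_PC + W2 * WQI_MB`, categorized on the
#' six-band scale of [categorize()].
#'
#' @param CWQI_PC Physico-chemical index, [cwqi_pc()].
#' @param WQI_MB Microbiological sub-index, [wqi_mb()].
#' @param scenario_id Scenario label used to look up `(W1, W2)`.
#' @param weights Optional explicit list `W1`, `W2` overriding the lookup.
#' @return List `cwqi`, `W1`, `W2`, `category`.
#' @export
#' @examples
#' modified_cwqi(80, 100, "S3")  # 0.7*80 + 0.3*100 = 86, "Good"
modified_cwqi <- function(CWQI_PC, WQI_MB, scenario_id, weights = NULL) {
  w <- if (is.null(weights)) ccme_weights(scenario_id) else weights
  if (abs(w$W1 + w$W2 - 1) > 1e-9)
    stop("sub-index weights must sum to 1", call. = FALSE)
  val <- w$W1 * CWQI_PC + w$W2 * WQI_MB
  list(cwqi = val, W1 = w$W1, W2 = w$W2, category = categorize(val))
}

#' Performance category of an index value
#'
#' The printed integer bands (95-100 Excellent, 89-94 Very Good, 80-88
#' Good, 65-79 Fair, 45-64 Marginal, 0-44 Poor) are extended to real
#' values with half-open intervals, assigning each gap to the lower
#' category's upper edge: `[95,100]` Excellent, `[89,95)` Very Good,
#' `[80,89)` Good, `[65,80)` Fair, `[45,65)` Marginal, `[0,45)` Poor.
#'
#' @param index Numeric value(s) in `[0, 100]`.
#' @return Character vector of categories.
#' @export
#' @examples
#' categorize(c(100, 96, 44, 45))
categorize <- function(index) {
  if (any(!is.finite(index) | index < 0 | index > 100))
    stop("index must lie in [0, 100]", call. = FALSE)
  as.character(cut(index, breaks = c(0, 45, 65, 80, 89, 95, 100),
                   labels = c("Poor", "Marginal", "Fair", "Good",
                              "Very Good", "Excellent"),
                   right = FALSE, include.lowest = TRUE))
}

#' Full modified-CWQI computation for one facility
#'
#' Splits the facility's monitoring series into physico-chemical and
#' biological parameters, summarizes compliance against the scenario
#' standards, and assembles factors, sub-indices, and the modified CWQI.
#'
#' @param data Monitoring tibble for a single facility.
#' @param standards A [scenario_standards()] object.
#' @param parameters Parameter definitions (supplies the group split).
#' @param excursion_cap Passed to [amplitude()].
#' @param strict Passed to [is_violation()].
#' @param scope_all_parameters If `TRUE`, F1's denominator counts the
#'   biological parameters too (they are still excluded from F2/F3 and
#'   handled by the microbiological sub-index). Default `FALSE`.
#' @param weights Optional explicit `(W1, W2)` list.
#' @return One-row tibble: `F1`, `F2`, `F3`, `nse`, `cwqi_pc`, `wqi_mb`,
#'   `cwqi`, `W1`, `W2`, `category`.
#' @export
ccme_index <- function(data, standards, parameters = cpi_parameters(),
                       excursion_cap = 100, strict = FALSE,
                       scope_all_parameters = FALSE, weights = NULL) {
  stopifnot(length(unique(data$facility_id)) == 1)
  grp <- parameters$group[match(data$parameter, parameters$code)]
  if (anyNA(grp))
    stop("unknown parameter code(s): ",
         paste(unique(data$parameter[is.na(grp)]), collapse = ", "),
         call. = FALSE)
  summarize_one <- function(d) {
    obj <- standards$objectives[[d$parameter[1]]]
    if (is.null(obj))
      stop("no objective for parameter ", d$parameter[1], " in scenario ",
           standards$scenario_id, call. = FALSE)
    summarize_compliance(d$value, obj, censored = d$censored, strict = strict)
  }
  pc <- data[grp != "biological", ]
  mb <- data[grp == "biological", ]
  pc_sum <- lapply(split(pc, pc$parameter), summarize_one)
  mb_sum <- lapply(split(mb, mb$parameter), summarize_one)

  sf <- scope_frequency(pc_sum)
  if (scope_all_parameters) {
    all_sum <- c(pc_sum, mb_sum)
    n_fail <- sum(vapply(all_sum, function(s) s$n_failed > 0, logical(1)))
    sf$F1 <- 100 * n_fail / length(all_sum)
  }
  amp <- amplitude(pc_sum, excursion_cap = excursion_cap)
  pc_idx <- cwqi_pc(sf$F1, sf$F2, amp$F3)
  mb_idx <- wqi_mb(mb_sum)
  mod <- modified_cwqi(pc_idx, mb_idx, standards$scenario_id, weights = weights)
  tibble::tibble(
    facility_id = data$facility_id[1], scenario = standards$scenario_id,
    F1 = sf$F1, F2 = sf$F2, F3 = amp$F3, nse = amp$nse,
    cwqi_pc = pc_idx, wqi_mb = mb_idx, cwqi = mod$cwqi,
    W1 = mod$W1, W2 = mod$W2, category = mod$category
  )
}
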