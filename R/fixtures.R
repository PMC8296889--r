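#' Bundled reference tables for the four-facility case study
#'
#' The package ships a reference dataset for four tertiary wastewater
#' treatment plants (WWTP-1 to WWTP-4) assessed under four reuse scenarios
#' (S1-S4):
#'
#' * `"standards"` — per-scenario objective limits (same as
#'   [read_standards_config()] on the bundled YAML).
#' * `"summary"` — per-facility monitoring summary statistics (min, mean,
#'   max, sd, cv); coliforms are flagged `nondetect` (always reported as
#'   `<1` MPN/100mL). Used to calibrate the synthetic generator.
#' * `"p_values"` — non-exceedance probabilities per scenario, facility
#'   and parameter (the realized output of the probability step).
#' * `"weights"` — final entropy-method importance weights per scenario
#'   (printed to two decimals; the rows sum to 0.97-0.99, a rounding
#'   artifact retained verbatim).
#' * `"ccme_weights"` — sub-index weights (W1, W2) per scenario.
#' * `"categories"` — performance category bands.
#'
#' @param name Which table.
#' @return A tibble (or a list of [scenario_standards()] for
#'   `"standards"`).
#' @export
#' @examples
#' load_reference_table("ccme_weights")
load_reference_table <- function(name = c("standards", "summary", "p_values",
                                          "weights", "ccme_weights",
                                          "categories")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "aquacpi")
  switch(name,
    standards = read_standards_config(path("standards.yaml")),
    summary = readr::read_csv(path("facility_summary.csv"),
      col_types = readr::cols(
        facility = readr::col_character(),
        parameter = readr::col_character(),
        unit = readr::col_character(),
        nondetect = readr::col_logical(),
        .default = readr::col_double()),
      progress = FALSE),
    p_values = readr::read_csv(path("nonexceedance.csv"),
      col_types = readr::cols(scenario = readr::col_character(),
                              facility = readr::col_character(),
                              parameter = readr::col_character(),
                              P = readr::col_double()),
      progress = FALSE),
    weights = readr::read_csv(path("entropy_weights.csv"),
      col_types = readr::cols(scenario = readr::col_character(),
                              parameter = readr::col_character(),
                              W = readr::col_double()),
      progress = FALSE),
    ccme_weights = readr::read_csv(path("ccme_weights.csv"),
      col_types = readr::cols(scenario = readr::col_character(),
                              W1 = readr::col_double(),
                              W2 = readr::col_double()),
      progress = FALSE),
    categories = readr::read_csv(path("categories.csv"),
      col_types = readr::cols(category = readr::col_character(),
                              low = readr::col_double(),
                              high = readr::col_double()),
      progress = FALSE)
  )
}

#' GWQI of the bundled reference dataset
#'
#' Runs the grey relational index on the bundled non-exceedance
#' probabilities and importance weights, per scenario.
#'
#' @param scenarios Scenario labels to compute.
#' @param xi Distinguishing coefficient.
#' @return Tibble: `scenario`, `facility_id`, `gwqi`.
#' @export
#' @examples
#' reference_gwqi("S1")
reference_gwqi <- function(scenarios = c("S1", "S2", "S3", "S4"), xi = 0.5) {
  pv <- load_reference_table("p_values")
  wt <- load_reference_table("weights")
  purrr::map_dfr(scenarios, function(sid) {
    pt <- as_p_table(
      dplyr::rename(pv[pv$scenario == sid, ], facility_id = "facility"), sid)
    g <- gwqi(pt, wt[wt$scenario == sid, c("parameter", "W")], xi = xi)
    dplyr::mutate(g, scenario = sid, .before = 1)
  })
}
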