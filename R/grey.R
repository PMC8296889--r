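#' Grey relational coefficients against perfect compliance
#'
#' Each facility x parameter non-exceedance probability is compared with
#' the constant reference sequence P = 100 (perfect compliance). With
#' deviations `delta = |100 - P|`, the grey relational coefficient is
#'
#'   coef = (dmin + xi * dmax) / (delta + xi * dmax)
#'
#' where `dmin`/`dmax` are the smallest and largest deviations over the
#' whole comparison set and `xi` is the distinguishing coefficient
#' (default 0.5, a moderate contrast). The coefficient lies in (0, 1]; the
#' entry closest to the reference scores highest. If every entry equals
#' the reference (`dmax = 0`) all coefficients are 1.
#'
#' @param p_table A `cpi_ptable` (see [build_p_table()], [as_p_table()]).
#' @param xi Distinguishing coefficient in (0, 1].
#' @param reference Reference probability, default 100 percent.
#' @param scope `"global"` takes `dmin`/`dmax` over all facilities and
#'   parameters of the table (the literal min-min / max-max reading);
#'   `"parameter"` computes the envelope within each parameter.
#' @return The table with `delta` and `coef` columns appended.
#' @export
grey_coefficients <- function(p_table, xi = 0.5, reference = 100,
                              scope = c("global", "parameter")) {
  scope <- match.arg(scope)
  if (!is.numeric(xi) || xi <= 0 || xi > 1)
    stop("distinguishing coefficient xi must lie in (0, 1]", call. = FALSE)
  if (nrow(p_table) == 0) stop("empty probability table", call. = FALSE)
  out <- dplyr::mutate(tibble::as_tibble(p_table),
                       delta = abs(reference - .data$P))
  env <- if (scope == "global") {
    dplyr::mutate(out, dmin = min(.data$delta), dmax = max(.data$delta))
  } else {
    out |>
      dplyr::group_by(.data$parameter) |>
      dplyr::mutate(dmin = min(.data$delta), dmax = max(.data$delta)) |>
      dplyr::ungroup()
  }
  coef <- ifelse(env$dmax == 0, 1,
                 (env$dmin + xi * env$dmax) / (env$delta + xi * env$dmax))
  out$coef <- coef
  structure(out, scenario_id = attr(p_table, "scenario_id"),
            class = class(p_table))
}

#' Grey relational analysis water quality index (GWQI)
#'
#' Weighted aggregation of the grey relational coefficients: per facility,
#' `GWQI = 100 * sum_j W_j coef_j` (the x100 scaling reports the grade on
#' the conventional 0-100 index scale; set `scale_to_100 = FALSE` for the
#' raw unit-interval grade). A facility in perfect compliance with every
#' objective scores 100 when the weights sum to 1.
#'
#' @inheritParams grey_coefficients
#' @param weights A `cpi_weights` tibble from [final_weights()], or any
#'   data frame with columns `parameter` and `W` covering every parameter
#'   in the table (e.g. the bundled reference weights).
#' @param scale_to_100 Report on the 0-100 scale (default).
#' @return Tibble: `facility_id`, `gwqi`, with attribute `scenario_id`.
#' @export
#' @examples
#' pt <- as_p_table(data.frame(
#'   facility_id = c("A", "A", "B", "B"),
#'   parameter = c("x", "y", "x", "y"),
#'   P = c(100, 100, 100, 50)), "S1")
#' w <- data.frame(parameter = c("x", "y"), W = c(0.5, 0.5))
#' gwqi(pt, w)   # A: 100, B: 66.67
gwqi <- function(p_table, weights, xi = 0.5, reference = 100,
                 scope = c("global", "parameter"), scale_to_100 = TRUE) {
  wt <- tibble::as_tibble(weights)[, c("parameter", "W")]
  miss <- setdiff(unique(p_table$parameter), wt$parameter)
  if (length(miss))
    stop("no weight for parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(wt$W < 0)) stop("weights must be nonnegative", call. = FALSE)
  gc <- grey_coefficients(p_table, xi = xi, reference = reference,
                          scope = scope)
  out <- tibble::as_tibble(gc) |>
    dplyr::left_join(wt, by = "parameter") |>
    dplyr::group_by(.data$facility_id) |>
    dplyr::summarise(gwqi = sum(.data$W * .data$coef), .groups = "drop")
  if (scale_to_100) out$gwqi <- 100 * out$gwqi
  attr(out, "scenario_id") <- attr(p_table, "scenario_id")
  out
}
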