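#' Build an expert Likert scoring matrix
#'
#' Rows are water quality parameters, columns are evaluation criteria
#' (default: C1 impact on geoenvironment, C2 plant growth, C3 livestock
#' safety, C4 human contact). Scores are 1-10 Likert values. When several
#' experts score independently, their matrices are combined by the
#' arithmetic mean of scores before the entropy computation.
#'
#' @param scores Numeric matrix (parameters x criteria), or a list of such
#'   matrices (one per expert) with identical dimnames.
#' @param parameters,criteria Optional dimnames if `scores` lacks them.
#' @return A validated numeric matrix of class `cpi_scores`.
#' @export
expert_scores <- function(scores, parameters = NULL, criteria = NULL) {
  if (is.list(scores) && !is.matrix(scores)) {
    stopifnot(length(scores) >= 1)
    scores <- Reduce(`+`, lapply(scores, as.matrix)) / length(scores)
  }
  scores <- as.matrix(scores)
  if (!is.null(parameters)) rownames(scores) <- parameters
  if (!is.null(criteria)) colnames(scores) <- criteria
  if (is.null(rownames(scores)))
    stop("score matrix needs parameter row names", call. = FALSE)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("C", seq_len(ncol(scores)))
  if (any(!is.finite(scores)) || any(scores < 1))
    stop("Likert scores must be finite and >= 1", call. = FALSE)
  structure(scores, class = c("cpi_scores", "matrix", "array"))
}

#' Shannon entropy and diversity of expert scores, per parameter
#'
#' For each parameter j the scores are normalized across the n criteria,
#' `p_ij = s_ij / sum_i(s_ij)`, and the entropy is
#' `E_j = -(1/ln n) * sum_i p_ij ln p_ij`, with the `0 ln 0 = 0` limit.
#' The diversity degree is `d_j = 1 - E_j`: a parameter scored uniformly
#' across criteria carries no discriminating information (`d = 0`), while
#' concentrated scoring raises `d`.
#'
#' @param scores Matrix from [expert_scores()] (or any parameters x
#'   criteria matrix with row names).
#' @param criterion_rescale If `TRUE`, each criterion column is divided by
#'   its column sum before the per-parameter normalization, removing
#'   criterion-level scale effects (the classical column-first orientation
#'   of the entropy weight method). Row-wise entropy is scale invariant, so
#'   this only matters when criterion column sums differ.
#' @return Tibble with columns `parameter`, `E`, `d`, plus attribute
#'   `alpha` (`1/ln n`).
#' @export
#' @examples
#' m <- expert_scores(rbind(A = c(9, 1), B = c(5, 5)))
#' entropy_vector(m)   # A: E = 0.469, d = 0.531; B: E = 1, d = 0
entropy_vector <- function(scores, criterion_rescale = FALSE) {
  m <- unclass(as.matrix(scores))
  n_crit <- ncol(m)
  if (n_crit < 2)
    stop("entropy needs at least 2 evaluation criteria (alpha = 1/ln n)",
         call. = FALSE)
  if (criterion_rescale) m <- sweep(m, 2, colSums(m), "/")
  p <- m / rowSums(m)
  plogp <- ifelse(p > 0, p * log(p), 0)
  alpha <- 1 / log(n_crit)
  E <- unname(-alpha * rowSums(plogp))
  E <- pmin(pmax(E, 0), 1)  # guard FP residue at the uniform/degenerate ends
  out <- tibble::tibble(parameter = rownames(m), E = E, d = 1 - E)
  attr(out, "alpha") <- alpha
  out
}

#' Final importance weights: entropy diversity combined with priori ratings
#'
#' Entropy weights `w_j = d_j / sum(d_j)` are blended with the experts'
#' a-priori subjective ratings (1/3/5/7/9 Likert scale) as
#' `W_j = priori_j w_j / sum(priori_j w_j)`; the final weights sum to 1.
#' In the degenerate case where every parameter is scored uniformly
#' (all `d_j = 0`) the weights fall back to the normalized priori ratings.
#'
#' @param scores Matrix from [expert_scores()].
#' @param priori Named numeric vector of a-priori ratings covering the same
#'   parameters (values from the 1/3/5/7/9 scale).
#' @param criterion_rescale Passed to [entropy_vector()].
#' @return A `cpi_weights` tibble: `parameter`, `E`, `d`, `w`, `priori`,
#'   `W`, with attribute `alpha`.
#' @export
final_weights <- function(scores, priori, criterion_rescale = FALSE) {
  ev <- entropy_vector(scores, criterion_rescale = criterion_rescale)
  if (is.null(names(priori)))
    stop("`priori` must be a named vector", call. = FALSE)
  miss <- setdiff(ev$parameter, names(priori))
  if (length(miss))
    stop("priori ratings missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pri <- as.numeric(priori[ev$parameter])
  if (any(pri <= 0)) stop("priori ratings must be positive", call. = FALSE)
  dsum <- sum(ev$d)
  if (dsum < 1e-12) {
    w <- rep(0, nrow(ev))
    W <- pri / sum(pri)
  } else {
    w <- ev$d / dsum
    W <- pri * w / sum(pri * w)
  }
  out <- tibble::tibble(parameter = ev$parameter, E = ev$E, d = ev$d,
                        w = w, priori = pri, W = W)
  attr(out, "alpha") <- attr(ev, "alpha")
  class(out) <- c("cpi_weights", class(out))
  out
}

#' Read an expert score matrix and priori ratings from CSV
#'
#' Score CSV columns: `parameter,criterion,score[,expert_id]`; multiple
#' experts are averaged. Priori CSV columns: `parameter,rating`.
#'
#' @param scores_path,priori_path CSV files.
#' @return List with `scores` (a [expert_scores()] matrix) and `priori`
#'   (named vector).
#' @export
read_expert_scores_csv <- function(scores_path, priori_path) {
  sc <- readr::read_csv(scores_path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("parameter", "criterion", "score") %in% names(sc)))
  if (!"expert_id" %in% names(sc)) sc$expert_id <- "E1"
  wide <- sc |>
    dplyr::group_by(.data$parameter, .data$criterion) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "criterion", values_from = "score")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$parameter
  pr <- readr::read_csv(priori_path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("parameter", "rating") %in% names(pr)))
  priori <- stats::setNames(pr$rating, pr$parameter)
  list(scores = expert_scores(m), priori = priori)
}
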