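# shared generators for randomized checks

# brute-force violation count, written independently of is_violation()
oracle_violations <- function(values, obj, censored = rep(FALSE, length(values))) {
  count <- 0L
  for (i in seq_along(values)) {
    v <- values[i]
    bad <- FALSE
    if (obj$bound_type == "upper") {
      if (v > obj$high) bad <- TRUE
    } else if (obj$bound_type == "lower") {
      if (v < obj$low) bad <- TRUE
    } else if (obj$bound_type == "range") {
      if (v < obj$low) bad <- TRUE
      if (v > obj$high) bad <- TRUE
    } else { # absent
      if (!censored[i] && v > 0) bad <- TRUE
    }
    if (bad) count <- count + 1L
  }
  count
}

random_objective <- function() {
  type <- sample(c("upper", "lower", "range", "absent"), 1)
  switch(type,
    upper = objective("upper", high = runif(1, 0.5, 20)),
    lower = objective("lower", low = runif(1, 0.5, 20)),
    range = {
      lims <- sort(runif(2, 0.5, 20))
      objective("range", low = lims[1], high = lims[2] + 0.1)
    },
    absent = objective("absent")
  )
}

random_series <- function(n = sample(2:40, 1), obj = NULL) {
  vals <- round(runif(n, 0, 25), 2)
  # include exact boundary hits now and then to exercise equality handling
  if (!is.null(obj) && obj$bound_type %in% c("upper", "range") && n > 2)
    vals[1] <- obj$high
  censored <- runif(n) < 0.2
  list(values = vals, censored = censored)
}

random_score_matrix <- function(k = 11, n_crit = 4) {
  m <- matrix(sample(1:10, k * n_crit, replace = TRUE), nrow = k)
  rownames(m) <- paste0("P", seq_len(k))
  colnames(m) <- paste0("C", seq_len(n_crit))
  m
}

random_priori <- function(params) {
  stats::setNames(sample(c(1, 3, 5, 7, 9), length(params), replace = TRUE),
                  params)
}
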