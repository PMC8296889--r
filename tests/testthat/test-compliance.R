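test_that("violation test is direction-aware with compliant boundaries", {
  expect_false(is_violation(10, objective("upper", high = 10)))
  expect_true(is_violation(10.01, objective("upper", high = 10)))
  expect_true(is_violation(5, objective("range", low = 6, high = 8.4)))
  expect_false(is_violation(6, objective("range", low = 6, high = 8.4)))
  expect_false(is_violation(8.4, objective("range", low = 6, high = 8.4)))
  expect_true(is_violation(0.1, objective("lower", low = 0.2)))
  # microbiological absence: censored non-detect complies, quantified presence fails
  expect_false(is_violation(1, objective("absent"), censored = TRUE))
  expect_true(is_violation(3, objective("absent"), censored = FALSE))
  expect_false(is_violation(0, objective("absent"), censored = FALSE))
  # strict mode flips boundary equality
  expect_true(is_violation(10, objective("upper", high = 10), strict = TRUE))
})

test_that("compliance summary counts and retains failed values", {
  s <- summarize_compliance(c(1, 2, 3, 4), objective("upper", high = 10))
  expect_equal(s$n_failed, 0)
  expect_equal(s$n_tests, 4)
  s <- summarize_compliance(c(10, 20), objective("upper", high = 5))
  expect_equal(s$n_failed, 2)
  s <- summarize_compliance(c(7, 7, 9, 5), objective("range", low = 6, high = 8.4))
  expect_equal(s$n_failed, 2)
  expect_equal(s$failed_values, c(9, 5))
  expect_error(summarize_compliance(numeric(0), objective("upper", high = 1)),
               "empty")
})

test_that("violation counts match a brute-force oracle on random inputs", {
  set.seed(42)
  for (i in 1:1000) {
    obj <- random_objective()
    s <- random_series(obj = obj)
    expect_equal(
      summarize_compliance(s$values, obj, censored = s$censored)$n_failed,
      oracle_violations(s$values, obj, s$censored)
    )
  }
})

test_that("non-exceedance probability follows the plotting-position rank", {
  expect_equal(nonexceedance_probability(c(1, 2, 3, 4),
                                         objective("upper", high = 10)), 80)
  # always failing: Pe would be 100, P clamps at the floor
  expect_equal(nonexceedance_probability(c(10, 20),
                                         objective("upper", high = 5)), 0.01)
  # never failing at n = 399: P = 100 * 399/400
  expect_equal(nonexceedance_probability(rep(1, 399),
                                         objective("upper", high = 10)), 99.75)
  # all-censored coliforms against an absence target short-circuit to the cap
  expect_equal(nonexceedance_probability(rep(1, 12), objective("absent"),
                                         censored = TRUE), 99.99)
})

test_that("P and Pe are complementary and the clamp band is respected", {
  set.seed(7)
  for (i in 1:300) {
    obj <- random_objective()
    s <- random_series(obj = obj)
    n <- length(s$values)
    m <- 1 + oracle_violations(s$values, obj, s$censored)
    p_raw <- 100 - 100 * m / (n + 1)
    p <- nonexceedance_probability(s$values, obj, censored = s$censored)
    if (obj$bound_type == "absent" && all(s$censored)) {
      expect_equal(p, 99.99)
    } else if (p_raw >= 0.01 && p_raw <= 99.99) {
      expect_equal(p, p_raw)                 # complement exact when unclamped
    } else {
      expect_true(p %in% c(0.01, 99.99))     # clamp only at the extremes
    }
    expect_gte(p, 0.01)
    expect_lte(p, 99.99)
  }
})

test_that("P is monotone under adding compliant or violating measurements", {
  set.seed(99)
  for (i in 1:200) {
    obj <- random_objective()
    if (obj$bound_type == "absent") next
    s <- random_series(obj = obj)
    p0 <- nonexceedance_probability(s$values, obj, censored = s$censored)
    viol <- switch(obj$bound_type,
                   upper = obj$high + 1, lower = obj$low - 1,
                   range = obj$high + 1)
    comp <- switch(obj$bound_type,
                   upper = obj$high - 0.1, lower = obj$low + 0.1,
                   range = (obj$low + obj$high) / 2)
    p_viol <- nonexceedance_probability(c(s$values, viol), obj,
                                        censored = c(s$censored, FALSE))
    p_comp <- nonexceedance_probability(c(s$values, comp), obj,
                                        censored = c(s$censored, FALSE))
    expect_lte(p_viol, p0 + 1e-9)
    expect_gte(p_comp, p0 - 1e-9)
  }
})

test_that("p-table covers each facility x parameter and flags missing objectives", {
  std <- read_standards_config()[["S1"]]
  d <- dplyr::bind_rows(
    monitoring_series("A", "TDS", c(100, 200, 9000)),
    monitoring_series("A", "pH", c(7, 7.2)),
    monitoring_series("B", "TDS", rep(100, 5))
  )
  pt <- build_p_table(d, std)
  expect_equal(nrow(pt), 3)
  expect_equal(attr(pt, "scenario_id"), "S1")
  a_tds <- pt[pt$facility_id == "A" & pt$parameter == "TDS", ]
  expect_equal(a_tds$n_failed, 1)
  expect_equal(a_tds$m, 2)
  expect_equal(a_tds$P, 100 - 100 * 2 / 4)

  d2 <- monitoring_series("A", "TDS", 1)
  d2$parameter <- "mystery"
  expect_error(build_p_table(d2, std), "mystery.*S1")
})
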