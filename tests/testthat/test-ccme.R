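mk_sum <- function(values, obj) summarize_compliance(values, obj)

test_that("scope and frequency factors are failure percentages", {
  up10 <- objective("upper", high = 10)
  fail_one <- mk_sum(c(1, 11), up10)
  pass <- mk_sum(c(1, 2), up10)
  sums <- c(rep(list(fail_one), 3), rep(list(pass), 8))
  sf <- scope_frequency(sums)
  expect_equal(sf$F1, 100 * 3 / 11, tolerance = 1e-9)  # 27.27
  # 10 failed of 400 tests -> F2 = 2.5
  sums2 <- c(list(mk_sum(c(rep(1, 190), rep(11, 10)), up10)),
             list(mk_sum(rep(1, 200), up10)))
  expect_equal(scope_frequency(sums2)$F2, 2.5)
  # no failures
  expect_equal(scope_frequency(list(pass))$F1, 0)
  expect_equal(scope_frequency(list(pass))$F2, 0)
  expect_error(scope_frequency(list()), "no compliance")
})

test_that("excursions dispatch per violated side and nse scales to F3", {
  expect_equal(amplitude(list(mk_sum(10, objective("upper", high = 5))))$excursions,
               1)
  # residual chlorine below a 0.2 floor: 0.2/0.1 - 1 = 1
  expect_equal(
    amplitude(list(mk_sum(0.1, objective("range", low = 0.2, high = 0.5))))$excursions,
    1)
  # range violated above: uses the upper side
  expect_equal(
    amplitude(list(mk_sum(1.0, objective("range", low = 0.2, high = 0.5))))$excursions,
    1.0 / 0.5 - 1)
  # excursions summing 2 over 4 tests: nse = 0.5, F3 = 0.5/0.015
  a <- amplitude(list(mk_sum(c(15, 5, 1, 1), objective("upper", high = 5))))
  expect_equal(a$nse, 0.5)
  expect_equal(a$F3, 0.5 / (0.01 * 0.5 + 0.01))  # 33.33
  # zero failed value under the lower-side ratio is capped, not infinite
  a0 <- amplitude(list(mk_sum(c(0, 1), objective("lower", low = 0.5))),
                  excursion_cap = 100)
  expect_equal(a0$excursions, 100)
  expect_true(is.finite(a0$nse))
})

test_that("F3 is increasing in nse with F3(1) = 50 and asymptote 100", {
  f3 <- function(nse) nse / (0.01 * nse + 0.01)
  expect_equal(f3(1), 50)
  nses <- c(0, 0.01, 0.1, 1, 5, 50, 1e6)
  vals <- f3(nses)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < 100))
})

test_that("physico-chemical index has norm ceiling 173.2 and floor 0", {
  expect_equal(cwqi_pc(0, 0, 0), 100)
  expect_equal(sqrt(3 * 100^2), 173.2, tolerance = 1e-4)
  expect_equal(cwqi_pc(100, 100, 100), 0)  # floored rounding residue
  expect_equal(cwqi_pc(27.27, 2.5, 33.33), 75.09, tolerance = 1e-3)
  # non-increasing in each factor
  expect_lte(cwqi_pc(30, 10, 10), cwqi_pc(20, 10, 10))
  expect_lte(cwqi_pc(10, 30, 10), cwqi_pc(10, 20, 10))
  expect_lte(cwqi_pc(10, 10, 30), cwqi_pc(10, 10, 20))
})

test_that("microbiological sub-index is the pass percentage", {
  up <- objective("upper", high = 1000)
  expect_equal(wqi_mb(list(mk_sum(rep(1, 52), up))), 100)
  expect_equal(wqi_mb(list(mk_sum(c(rep(1, 39), rep(2000, 13)), up))), 75)
  expect_equal(wqi_mb(list(mk_sum(rep(2000, 5), up))), 0)
  expect_error(wqi_mb(list()), "microbiological")
})

test_that("modified index blends sub-indices with scenario weights", {
  r <- modified_cwqi(80, 100, "S3")
  expect_equal(r$cwqi, 86)  # 0.7*80 + 0.3*100
  expect_equal(r$category, "Good")
  expect_equal(modified_cwqi(100, 100, "S1")$cwqi, 100)
  w2 <- ccme_weights("S2")
  expect_equal(c(w2$W1, w2$W2), c(0.8, 0.2))
  expect_error(ccme_weights("S9"), "no sub-index weights")
  expect_error(modified_cwqi(80, 100, "S1", weights = list(W1 = 0.5, W2 = 0.4)),
               "sum to 1")
})

test_that("categorization uses half-open bands over the full scale", {
  expect_equal(categorize(96), "Excellent")
  expect_equal(categorize(100), "Excellent")
  expect_equal(categorize(95), "Excellent")
  expect_equal(categorize(94.99), "Very Good")
  expect_equal(categorize(89), "Very Good")
  expect_equal(categorize(88.5), "Good")
  expect_equal(categorize(80), "Good")
  expect_equal(categorize(79.9), "Fair")
  expect_equal(categorize(65), "Fair")
  expect_equal(categorize(64.9), "Marginal")
  expect_equal(categorize(45), "Marginal")
  expect_equal(categorize(44), "Poor")
  expect_equal(categorize(0), "Poor")
  expect_error(categorize(101), "0, 100")
  expect_error(categorize(-1), "0, 100")
})

test_that("a facility with zero failures scores 100 under every weighting", {
  d <- dplyr::bind_rows(
    monitoring_series("A", "TDS", rep(400, 10)),
    monitoring_series("A", "pH", rep(7, 10)),
    monitoring_series("A", "Cl2", rep(0.3, 10)),
    monitoring_series("A", "TC", rep(1, 10), censored = TRUE, detection_limit = 1),
    monitoring_series("A", "FC", rep(1, 10), censored = TRUE, detection_limit = 1)
  )
  for (sid in c("S1", "S2", "S3", "S4")) {
    std <- read_standards_config()[[sid]]
    r <- ccme_index(d, std)
    expect_equal(r$cwqi, 100)
    expect_equal(r$category, "Excellent")
  }
})
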