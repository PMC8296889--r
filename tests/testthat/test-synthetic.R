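test_that("the same seed reproduces a campaign byte-for-byte", {
  c1 <- generate_campaign("WWTP-1", n_days = 30, seed = 21)
  c2 <- generate_campaign("WWTP-1", n_days = 30, seed = 21)
  expect_identical(c1, c2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_monitoring_csv(c1, f1)
  write_monitoring_csv(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  c3 <- generate_campaign("WWTP-1", n_days = 30, seed = 22)
  expect_false(identical(c1$value, c3$value))
})

test_that("coliform profiles emit censored non-detects that never violate absence", {
  camp <- generate_campaign("WWTP-3", n_days = 365, seed = 2)
  tc <- camp[camp$parameter == "TC", ]
  expect_equal(nrow(tc), 365)
  expect_true(all(tc$censored))
  expect_true(all(tc$detection_limit == 1))
  s <- summarize_compliance(tc$value, objective("absent"), censored = tc$censored)
  expect_equal(s$n_failed, 0)
  expect_equal(nonexceedance_probability(tc$value, objective("absent"),
                                         censored = tc$censored), 99.99)
})

test_that("samples respect the declared ranges everywhere", {
  summ <- load_reference_table("summary")
  for (f in unique(summ$facility)) {
    prof <- parameter_profiles(summ, f)
    camp <- generate_campaign(f, prof, n_days = 120, seed = 5)
    for (i in seq_len(nrow(prof))) {
      p <- prof[i, ]
      if (p$distribution %in% c("constant_nondetect", "constant")) next
      v <- camp$value[camp$parameter == p$parameter]
      expect_gte(min(v), p$min)
      expect_lte(max(v), p$max)
    }
  }
})

test_that("a year-long TDS series recovers its calibration mean within 3 SE", {
  prof <- parameter_profiles(facility = "WWTP-1")
  tds_prof <- prof[prof$parameter == "TDS", ]
  camp <- generate_campaign("WWTP-1", tds_prof, n_days = 365, seed = 101)
  se <- tds_prof$sd / sqrt(365)
  expect_lt(abs(mean(camp$value) - tds_prof$mean), 3 * se)
})

test_that("mildly truncated profiles recover mean and sd within 4 SE", {
  # restrict to profiles whose bounds sit >= 2 sd from the mean, where
  # rejection-clipping leaves the moments essentially untouched
  summ <- load_reference_table("summary")
  for (f in unique(summ$facility)) {
    prof <- parameter_profiles(summ, f)
    prof <- prof[!prof$distribution %in% c("constant", "constant_nondetect") &
                 prof$mean - prof$min >= 2 * prof$sd &
                 prof$max - prof$mean >= 2 * prof$sd, ]
    for (i in seq_len(nrow(prof))) {
      p <- prof[i, ]
      camp <- generate_campaign(f, p, n_days = 365, seed = 300 + i)
      se_mean <- p$sd / sqrt(365)
      se_sd <- p$sd / sqrt(2 * 364)
      expect_lt(abs(mean(camp$value) - p$mean), 4 * se_mean)
      expect_lt(abs(sd(camp$value) - p$sd), 6 * se_sd)
    }
  }
})

test_that("an infeasible profile errors instead of looping forever", {
  # sampling window sits ~19000 sd away from the distribution's center
  prof <- tibble::tibble(parameter = "TDS", distribution = "truncated_normal",
                         mean = 10, sd = 0.01, min = 200, max = 201,
                         detection_limit = NA_real_)
  expect_error(generate_campaign("X", prof, n_days = 10, seed = 1,
                                 start_date = as.Date("2020-01-01")),
               "infeasible")
})

test_that("synthetic expert scores follow the scenario's qualitative ordering", {
  s1 <- generate_expert_scores("S1", seed = 9)
  s2 <- generate_expert_scores("S2", seed = 9)
  expect_true(all(s1$scores >= 1 & s1$scores <= 10))
  expect_true(all(s1$scores == round(s1$scores)))
  expect_lt(s1$scores["TC", "C4"], s2$scores["TC", "C4"])
  expect_lt(s1$scores["FC", "C4"], s2$scores["FC", "C4"])
  expect_true(attr(s1$scores, "synthetic"))
  # downstream invariant: weights from any generated matrix sum to 1
  for (sid in c("S1", "S2", "S3", "S4")) {
    g <- generate_expert_scores(sid, seed = 17)
    w <- final_weights(g$scores, g$priori)
    expect_equal(sum(w$W), 1, tolerance = 1e-12)
  }
})

test_that("generated campaigns run the full pipeline to in-range indices", {
  summ <- load_reference_table("summary")
  camp <- dplyr::bind_rows(lapply(seq_along(unique(summ$facility)), function(i) {
    f <- unique(summ$facility)[i]
    generate_campaign(f, parameter_profiles(summ, f), n_days = 60,
                      seed = 400 + i)
  }))
  res <- assess(camp)
  expect_equal(nrow(res), 16)
  expect_true(all(res$gwqi >= 0 & res$gwqi <= 100))
  expect_true(all(res$cwqi >= 0 & res$cwqi <= 100))
  expect_true(all(res$category %in% c("Excellent", "Very Good", "Good",
                                      "Fair", "Marginal", "Poor")))
})
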