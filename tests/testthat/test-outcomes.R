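test_that("reading averages match brute-force sums", {
  expect_equal(average_readings(data.frame(sbp = c(100, 102, 104),
                                           dbp = c(60, 62, 64))),
               c(sbp_mean = 102, dbp_mean = 62))
  expect_warning(one <- average_readings(data.frame(sbp = 111, dbp = 71)),
                 "at least 3")
  expect_equal(one, c(sbp_mean = 111, dbp_mean = 71))
  set.seed(20)
  r <- data.frame(sbp = rnorm(7, 100, 10), dbp = rnorm(7, 60, 8))
  expect_equal(average_readings(r),
               c(sbp_mean = sum(r$sbp) / 7, dbp_mean = sum(r$dbp) / 7))
  expect_error(average_readings(data.frame(sbp = numeric(), dbp = numeric())),
               "no readings")
})

test_that("static classifier truth table, boundaries included", {
  expect_true(classify_elevated_static(110, 60))    # SBP boundary inclusive
  expect_false(classify_elevated_static(105, 70))   # DBP boundary strict
  expect_true(classify_elevated_static(105, 70.5))
  expect_false(classify_elevated_static(109.99, 70))
  expect_true(classify_elevated_static(200, 40))
  expect_equal(classify_elevated_static(c(110, 105, 90), c(60, 70, 80)),
               c(TRUE, FALSE, TRUE))
  expect_error(classify_elevated_static(-5, 60), "negative")
  expect_error(classify_elevated_static(NA, 60), "finite")
})

test_that("static classifier is monotone in both components", {
  set.seed(21)
  s <- runif(200, 80, 130)
  d <- runif(200, 50, 85)
  base <- classify_elevated_static(s, d)
  up_s <- classify_elevated_static(s + runif(200, 0, 15), d)
  up_d <- classify_elevated_static(s, d + runif(200, 0, 15))
  expect_true(all(up_s >= base))
  expect_true(all(up_d >= base))
})

test_that("percentile classifier interpolates the reference linearly", {
  ref <- toy_bp_reference()
  gr <- toy_growth_reference()
  # midpoint between tabulated height percentiles: hand interpolation
  r11 <- ref[ref$sex == "male" & ref$age == 11, ]
  r11 <- r11[order(r11$height_percentile), ]
  hp_mid <- (r11$height_percentile[2] + r11$height_percentile[3]) / 2
  want_s90 <- (r11$sbp_p90[2] + r11$sbp_p90[3]) / 2
  # choose the height giving exactly that percentile under the growth ref
  g <- gr[gr$sex == "male" & gr$age == 11, ]
  height <- g$height_mean + g$height_sd * qnorm(hp_mid / 100)
  got <- bvckmr:::.ref_threshold(ref, "male", 11,
                                 height_percentile(height, "male", 11, gr),
                                 "sbp_p90")
  expect_equal(got, want_s90, tolerance = 1e-6)

  # boundary inclusive: at exactly the threshold -> elevated
  d90 <- bvckmr:::.ref_threshold(ref, "male", 11, hp_mid, "dbp_p90")
  expect_true(classify_elevated_percentile(want_s90, 40, "male", 11, height,
                                           ref, gr))
  expect_false(classify_elevated_percentile(want_s90 - 0.01, d90 - 0.01,
                                            "male", 11, height, ref, gr))
  expect_true(classify_elevated_percentile(80, d90, "male", 11, height,
                                           ref, gr))
})

test_that("percentile classifier rejects out-of-range ages naming the bound", {
  ref <- toy_bp_reference()
  gr <- toy_growth_reference()
  expect_error(classify_elevated_percentile(100, 60, "male", 25, 150, ref, gr),
               "outside reference range")
})

test_that("static prevalence exceeds toy percentile prevalence on the default cohort", {
  co <- default_cohort()
  p_static <- mean(elevated_bp(co, "static"))
  p_pct <- mean(elevated_bp(co, "percentile",
                            reference = toy_bp_reference(),
                            growth = toy_growth_reference()))
  expect_gt(p_static, p_pct)
  # a plausible school-age prevalence, not a degenerate classifier
  expect_gt(p_static, 0.05)
  expect_lt(p_static, 0.7)
})
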