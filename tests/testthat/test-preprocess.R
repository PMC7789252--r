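test_that("specific-gravity adjustment reproduces the worked values", {
  expect_equal(adjust_specific_gravity(1.0, 1.020), 1.0)
  expect_equal(adjust_specific_gravity(1.0, 1.010), 2.0)
  expect_equal(adjust_specific_gravity(2.0, 1.040), 1.0)
  expect_error(adjust_specific_gravity(1.0, 0.999), "specific gravity")
  expect_error(adjust_specific_gravity(-1, 1.02), "positive")
})

test_that("adjustment at the reference SG is the identity for any concentration", {
  set.seed(11)
  conc <- exp(rnorm(200, 0, 2))
  expect_equal(adjust_specific_gravity(conc, rep(1.020, 200)), conc)
  # and scales by (ref-1)/(sg-1) in general
  sg <- runif(200, 1.005, 1.035)
  expect_equal(adjust_specific_gravity(conc, sg),
               conc * 0.020 / (sg - 1))
})

test_that("mean +/- k SD screen agrees with a brute-force pass", {
  v <- c(0, 0, 0, 0, 100)
  keep <- exclude_outliers(v, k = 4)
  # brute-force oracle: one direct mean/SD computation
  z <- (v - mean(v)) / sd(v)
  expect_equal(unclass(keep)[seq_along(v)], abs(z) <= 4,
               ignore_attr = TRUE)
  expect_true(all(keep))  # max |z| at n=5 is below 4

  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(50, sd = runif(1, 0.5, 5))
    k <- runif(1, 1, 4)
    got <- exclude_outliers(x, k)
    want <- abs((x - mean(x)) / sd(x)) <= k
    expect_equal(unclass(got)[seq_along(x)], want, ignore_attr = TRUE)
  }
})

test_that("screen edge cases: constant input, k = Inf, total exclusion", {
  expect_true(all(exclude_outliers(rep(3.3, 10))))
  expect_true(all(exclude_outliers(rnorm(20), k = Inf)))
  # two distinct values both sit at |z| = 0.707; small k rejects all
  expect_error(exclude_outliers(c(0, 1), k = 0.5), "every value")
  expect_error(exclude_outliers(c(1), k = 4), "two finite")
})

test_that("log2 standardisation matches the hand-computed oracle", {
  em <- log2_standardize(data.frame(Mo = c(1, 2, 4)))
  # log2 -> {0,1,2}; centre 1; sample SD (n-1) = 1
  expect_equal(unname(drop(em[, "Mo"])), c(-1, 0, 1))
  expect_equal(unname(attr(em, "center")["Mo"]), 1)
  expect_equal(unname(attr(em, "scale")["Mo"]), 1)
})

test_that("standardised columns have mean 0 / SD 1 and the transform round-trips", {
  set.seed(13)
  X <- data.frame(As = rlnorm(40, 1, 0.5), Mo = rlnorm(40, 4, 0.8))
  em <- log2_standardize(X)
  expect_equal(unname(colMeans(em)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(em, 2, sd)), c(1, 1), tolerance = 1e-12)
  # inverse(forward(x)) = x elementwise
  expect_equal(unstandardize(em, em[, "Mo"], "Mo"), X$Mo, tolerance = 1e-10)
  expect_equal(standardize_conc(em, X$Mo, "Mo"), unname(em[, "Mo"]),
               tolerance = 1e-10)
  expect_error(log2_standardize(data.frame(Mo = c(1, -2, 4))),
               "row 2, metal Mo")
})

test_that("standardisation is invariant to positive rescaling of a raw column", {
  set.seed(14)
  x <- rlnorm(30, 2, 1)
  e1 <- log2_standardize(data.frame(Mo = x))
  e2 <- log2_standardize(data.frame(Mo = 7.3 * x))
  expect_equal(unclass(e1)[, 1], unclass(e2)[, 1], tolerance = 1e-12)
})

test_that("LOD policies: machine value retained by default, LOD/sqrt(2) on request", {
  panel <- data.frame(subject_id = c("a", "b"), specific_gravity = c(1.02, 1.02),
                      Sb = c(0.0015, 0.05))
  flags <- matrix(c(TRUE, FALSE), 2, 1, dimnames = list(NULL, "Sb"))
  attr(panel, "below_lod") <- flags
  attr(panel, "lod") <- c(Sb = 0.002)
  kept <- handle_lod(panel)
  expect_equal(kept$Sb, panel$Sb)                    # values untouched
  expect_equal(attr(kept, "below_lod"), flags)       # flag preserved
  sub <- handle_lod(panel, "lod_sqrt2")
  expect_equal(sub$Sb[1], 0.002 / sqrt(2))
  expect_equal(sub$Sb[2], 0.05)
  # no flags: panel unchanged under either policy
  p2 <- data.frame(subject_id = "a", specific_gravity = 1.02, Sb = 0.05)
  expect_identical(handle_lod(p2, "lod_sqrt2"), p2)
})

test_that("full pipeline: fixed order, exclusion log, exact recovery of adjusted scale", {
  co <- default_cohort()
  res <- preprocess_metals(co$panel)
  expect_equal(max(abs(colMeans(res$exposures))), 0, tolerance = 1e-12)
  expect_equal(unname(apply(res$exposures, 2, sd)), rep(1, 8),
               tolerance = 1e-12)
  # SG adjustment inverts the simulated dilution exactly
  adj <- attr(co$panel, "adjusted")
  expect_equal(unname(as.matrix(res$adjusted[METALS])), unname(adj),
               tolerance = 1e-10)
  expect_equal(res$steps[1], "lod_policy:retain_machine_value")
  expect_match(res$steps[3], "log2,k=4")   # screen after SG adjustment
  expect_s3_class(res$exclusions, "data.frame")
  expect_true(all(c("subject_id", "metal", "value", "lower", "upper") %in%
                  colnames(res$exclusions)))
  # screens on the log2 scale by default; a wild raw value must go
  panel2 <- co$panel
  panel2$Mo[1] <- panel2$Mo[1] * 1e6
  res2 <- preprocess_metals(panel2)
  expect_false(res2$retained[1])
  expect_true("Mo" %in% res2$exclusions$metal)
})
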