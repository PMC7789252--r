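test_that("schedule bookkeeping follows (niter - burnin) / thin", {
  expect_equal(mcmc_retained(100000, 50000, 10), 5000)
  expect_equal(mcmc_retained(2000), 1000)
  expect_equal(mcmc_retained(1001, 500, 3), 167)
  expect_error(mcmc_retained(100, 100), "burnin")
  co <- default_cohort()
  fit <- shared_sbp_fit()
  expect_equal(nrow(fit$draws$h1),
               mcmc_retained(fit$schedule$niter, fit$schedule$burnin,
                             fit$schedule$thin))
  expect_true(all(fit$draws$sigma_e2 > 0))
  expect_true(all(fit$draws$sigma_b2 > 0))
})

test_that("fixed-effect summaries follow the credible-interval convention", {
  fake <- list(draws = list(theta = matrix(3.3, 200, 1,
                                           dimnames = list(NULL, "x"))))
  s <- summarize_fixed_effects(fake)
  expect_equal(s$lower, 3.3)
  expect_equal(s$upper, 3.3)
  expect_true(s$significant)  # degenerate at a nonzero constant

  fake0 <- list(draws = list(theta = matrix(c(-1, 1), 200, 1,
                                            dimnames = list(NULL, "x"))))
  expect_false(summarize_fixed_effects(fake0)$significant)

  set.seed(30)
  fakeN <- list(draws = list(theta = matrix(rnorm(10000), ncol = 1,
                                            dimnames = list(NULL, "z"))))
  s3 <- summarize_fixed_effects(fakeN)
  expect_equal(s3$lower, -1.96, tolerance = 0.04)
  expect_equal(s3$upper, 1.96, tolerance = 0.04)

  expect_warning(summarize_fixed_effects(
    list(draws = list(theta = matrix(0, 10, 1)))), "retained draws")
})

test_that("posterior mean of h1 matches the closed-form conjugate solution", {
  # single visit, everything but h1 pinned: the sampler draws iid from
  # the exact Gaussian posterior, whose mean is the GP ridge solution
  set.seed(31)
  n <- 60
  Z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("Mo", "Pb", "Cd")))
  r <- c(Mo = 0.4, Pb = 0.2, Cd = 0)
  tau2 <- 2
  sigma2 <- 1
  K <- gaussian_kernel(Z, r = r)
  htrue <- drop(chol(tau2 * K) %*% rnorm(n))  # an arbitrary smooth truth
  y <- htrue + rnorm(n, 0, sqrt(sigma2))
  fit <- bvckmr(y, Z, X = NULL, id = seq_len(n), age = rep(4, n),
                niter = 1500, burnin = 500,
                control = bvckmr_control(
                  include_h2 = FALSE, include_ranef = FALSE,
                  fix = list(r1 = r, tau1_2 = tau2, sigma_e2 = sigma2,
                             theta = c(0, 0))),
                seed = 32)
  oracle <- gp_conditional(K, y, tau2, sigma2)$mean
  hbar <- colMeans(fit$draws$h1)
  mcse <- apply(fit$draws$h1, 2, sd) / sqrt(nrow(fit$draws$h1))
  expect_gt(mean(abs(hbar - oracle) <= 3 * mcse), 0.95)
})

test_that("adding a constant to the outcome shifts the intercept, not the surfaces", {
  set.seed(33)
  n <- 60
  Z <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("Mo", "Pb")))
  id <- rep(seq_len(n), each = 2)
  age <- rep(c(4, 11), n)
  y <- 90 + 1.5 * (age - 4) + 2 * Z[id, "Mo"] + rnorm(2 * n, 0, 2)
  f0 <- bvckmr(y, Z, id = id, age = age, niter = 1200, burnin = 600,
               seed = 34)
  fc <- bvckmr(y + 50, Z, id = id, age = age, niter = 1200, burnin = 600,
               seed = 34)
  shift <- coef(fc)[["intercept"]] - coef(f0)[["intercept"]]
  expect_equal(shift, 50, tolerance = 5)
  # the identified combination gamma1 + mean(h1) shifts by c exactly
  lev0 <- coef(f0)[["intercept"]] + mean(colMeans(f0$draws$h1))
  levc <- coef(fc)[["intercept"]] + mean(colMeans(fc$draws$h1))
  expect_equal(levc - lev0, 50, tolerance = 1)
  c0 <- iqr_contrast(f0, "Mo", "h1", ndraws = 150)
  cc <- iqr_contrast(fc, "Mo", "h1", ndraws = 150)
  expect_equal(cc$estimate, c0$estimate, tolerance = 1)
  # analytic oracle for a linear surface: slope x interquartile range
  expect_equal(c0$estimate,
               unname(2 * diff(quantile(Z[, "Mo"], c(0.25, 0.75)))),
               tolerance = 0.3)
})

test_that("chains are reproducible and subject-order invariant in summaries", {
  co <- default_cohort()
  f1 <- fit_bvckmr(co, "dbp", niter = 400, burnin = 200, seed = 35)
  f2 <- fit_bvckmr(co, "dbp", niter = 400, burnin = 200, seed = 35)
  expect_identical(f1$draws, f2$draws)

  # permuting input rows leaves the per-subject posterior labelled right
  set.seed(36)
  v <- co$visits
  perm <- sample(nrow(v))
  f3 <- bvckmr(v$dbp[perm], co$exposures, X = NULL,
               id = v$subject_id[perm], age = v$age[perm],
               niter = 400, burnin = 200, seed = 37)
  # same subjects, same data: posterior means agree within MC error
  common <- intersect(f1$subjects, f3$subjects)
  m1 <- colMeans(f1$draws$h1)[common]
  m3 <- colMeans(f3$draws$h1)[common]
  expect_gt(cor(m1, m3), 0.85)
})

test_that("divergence and input errors are reported", {
  Z <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("Mo", "Pb")))
  expect_error(bvckmr(c(rnorm(9), NA), Z, id = 1:10, age = rep(4, 10)),
               "non-finite outcome")
  expect_error(bvckmr(rnorm(10), Z, id = 1:10, age = rep(4, 10),
                      niter = 100, burnin = 100), "burnin")
})
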