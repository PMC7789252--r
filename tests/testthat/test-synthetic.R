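test_that("truth spec validates its invariants", {
  expect_s3_class(truth_spec(), "truth_spec")
  badC <- diag(8)
  dimnames(badC) <- list(METALS, METALS)
  badC["As", "Cd"] <- badC["Cd", "As"] <- 1.2   # breaks positive definiteness
  expect_error(truth_spec(corr = badC), "eigenvalue")
  badS <- .default_corr()
  badS["As", "Cd"] <- 0.3                       # asymmetric
  expect_error(truth_spec(corr = badS), "symmetric")
})

test_that("simulated metals reproduce the configured marginals and correlations", {
  spec <- truth_spec(n_subjects = 10000, seed = 1)
  set.seed(spec$seed)
  panel <- simulate_metals(spec)
  # fidelity is assessed on the dilution-corrected scale the calibration
  # targets: SG-adjustment exactly recovers the latent draw
  adj <- adjust_specific_gravity(as.matrix(panel[METALS]),
                                 panel$specific_gravity)
  gm_mo <- exp(mean(log(adj[, "Mo"])))
  expect_lt(abs(gm_mo / 58.15 - 1), 0.03)
  r_cdpb <- cor(log(adj[, "Cd"]), log(adj[, "Pb"]))
  expect_lt(abs(r_cdpb - 0.45), 0.03)
  expect_true(all(panel$specific_gravity > 1.001 &
                  panel$specific_gravity < 1.040))
})

test_that("identity correlation gives independent metals", {
  C <- diag(8)
  dimnames(C) <- list(METALS, METALS)
  spec <- truth_spec(n_subjects = 10000, corr = C, seed = 2)
  set.seed(spec$seed)
  panel <- simulate_metals(spec)
  adj <- adjust_specific_gravity(as.matrix(panel[METALS]),
                                 panel$specific_gravity)
  R <- cor(log(adj))
  expect_lt(max(abs(R[upper.tri(R)])), 0.03)
})

test_that("degenerate spread collapses every draw onto the geometric mean", {
  spec <- truth_spec(n_subjects = 50, log_gsd = setNames(rep(0, 8), METALS),
                     seed = 3)
  set.seed(spec$seed)
  panel <- simulate_metals(spec)
  adj <- adjust_specific_gravity(as.matrix(panel[METALS]),
                                 panel$specific_gravity)
  for (m in METALS)
    expect_equal(unname(adj[, m]), rep(exp(spec$log_gm[[m]]), 50),
                 tolerance = 1e-10)
})

test_that("empirical log-scale covariance converges to the specification", {
  spec <- truth_spec(n_subjects = 10000, seed = 4)
  set.seed(spec$seed)
  panel <- simulate_metals(spec)
  adj <- adjust_specific_gravity(as.matrix(panel[METALS]),
                                 panel$specific_gravity)
  target <- diag(spec$log_gsd) %*% spec$corr %*% diag(spec$log_gsd)
  frob <- norm(cov(log(adj)) - target, "F") / norm(target, "F")
  expect_lt(frob, 0.05)
})

test_that("noise-free null trajectories equal the fixed part exactly", {
  spec <- truth_spec(n_subjects = 30, effects = "null", seed = 5)
  spec$sbp$sigma_b2 <- spec$sbp$sigma_e2 <- 0
  spec$dbp$sigma_b2 <- spec$dbp$sigma_e2 <- 0
  co <- simulate_cohort(spec)
  expect_equal(co$visits$sbp,
               spec$sbp$gamma1 + spec$sbp$gamma2 * (co$visits$age - 4),
               tolerance = 1e-10)
  expect_equal(co$visits$dbp,
               spec$dbp$gamma1 + spec$dbp$gamma2 * (co$visits$age - 4),
               tolerance = 1e-10)
})

test_that("a known linear surface is recovered by least squares on the true design", {
  # independent oracle: OLS of y on the oracle features
  spec <- truth_spec(n_subjects = 2000, effects = "null", seed = 6)
  cc <- 2.4
  spec$sbp$h1_fn <- function(Z) cc * Z[, "Mo"]
  co <- simulate_cohort(spec)
  Z <- co$exposures
  d <- co$visits
  d$mo <- Z[match(d$subject_id, rownames(Z)), "Mo"]
  ols <- coef(lm(sbp ~ I(age - 4) + mo, data = d))
  se <- sqrt(diag(vcov(lm(sbp ~ I(age - 4) + mo, data = d))))["mo"]
  expect_lt(abs(ols[["mo"]] - cc), 4 * se)
})

test_that("default calibration gives rising mean SBP across the three visits", {
  co <- default_cohort()
  m <- tapply(co$visits$sbp, co$visits$visit, mean)
  expect_true(m[["4"]] < m[["6"]] && m[["6"]] < m[["11"]])
  # and sits in the right neighbourhood of the calibration anchors
  expect_lt(abs(m[["4"]] - 90.6), 3)
  expect_lt(abs(m[["11"]] - 105.8), 3)
})

test_that("variance decomposition holds under the null mixture", {
  spec <- truth_spec(n_subjects = 4000, effects = "null", seed = 7)
  co <- simulate_cohort(spec)
  v <- co$visits
  # remove the age trend, then decompose
  resid <- v$sbp - spec$sbp$gamma1 - spec$sbp$gamma2 * (v$age - 4)
  tot <- var(resid)
  expect_lt(abs(tot - (spec$sbp$sigma_b2 + spec$sbp$sigma_e2)) / tot, 0.1)
  w <- unsplit(lapply(split(resid, v$subject_id), function(x) x - mean(x)),
               v$subject_id)
  icc_hat <- 1 - var(w) / tot * 3 / 2   # within-var scaled by (n_i-1)/n_i
  expect_lt(abs(icc_hat - 0.5), 0.06)
})

test_that("identical seeds reproduce the cohort bit for bit", {
  s <- truth_spec(n_subjects = 40, seed = 8)
  expect_identical(simulate_cohort(s), simulate_cohort(s))
})

test_that("missing visit ages are rejected with subject and visit named", {
  spec <- truth_spec(n_subjects = 10, seed = 9)
  set.seed(9)
  panel <- simulate_metals(spec)
  covs <- simulate_covariates(spec)
  covs$visits$age[5] <- NA
  em <- log2_standardize(as.data.frame(attr(panel, "adjusted")))
  expect_error(simulate_bp(spec, em, covs),
               sprintf("subject %s, visit %d", covs$visits$subject_id[5],
                       covs$visits$visit[5]))
})

test_that("stored oracle surfaces match the truth functions at the stored exposures", {
  co <- default_cohort()
  expect_equal(co$oracle$h1_sbp,
               unname(co$truth$sbp$h1_fn(as.matrix(co$exposures))))
  expect_equal(co$oracle$h2_dbp,
               unname(co$truth$dbp$h2_fn(as.matrix(co$exposures))))
  expect_equal(nrow(co$visits), 3 * nrow(co$panel))  # three visits each
})
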