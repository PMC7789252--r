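test_that("PIP tallies match a hand-enumerated indicator table", {
  groups <- list(toxic = c("As", "Cd"), essential = c("Mo", "Se"))
  act <- cbind(toxic = c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1),
               essential = rep(1, 10))
  sel <- cbind(toxic = ifelse(act[, 1] == 1,
                              c("As", "Cd", NA, "As", NA, "As", "Cd", NA,
                                "As", "As"), NA),
               essential = c(rep("Mo", 6), rep("Se", 4)))
  fake <- list(draws = list(active = act, sel = sel), groups = groups)
  p <- compute_pips(fake)
  expect_equal(p$groups$pip, c(0.7, 1.0))
  m <- p$metals
  # brute-force tally oracle
  expect_equal(m$cond_pip[m$metal == "As"], 5 / 7)
  expect_equal(m$cond_pip[m$metal == "Cd"], 2 / 7)
  expect_equal(m$cond_pip[m$metal == "Mo"], 0.6)
  expect_equal(m$cond_pip[m$metal == "Se"], 0.4)
  # conditional PIPs sum to one within each active group
  expect_equal(sum(m$cond_pip[m$group == "toxic"]), 1)
  expect_equal(sum(m$cond_pip[m$group == "essential"]), 1)
})

test_that("a never-active group reports PIP 0 and undefined conditionals", {
  groups <- list(toxic = c("As", "Cd"), essential = c("Mo", "Se"))
  act <- cbind(toxic = rep(0, 5), essential = rep(1, 5))
  sel <- cbind(toxic = rep(NA_character_, 5), essential = rep("Mo", 5))
  p <- compute_pips(list(draws = list(active = act, sel = sel),
                         groups = groups))
  expect_equal(p$groups$pip, c(0, 1))
  expect_true(all(is.na(p$metals$cond_pip[p$metals$group == "toxic"])))
})

test_that("probit BKMR validates inputs", {
  Z <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("Mo", "Pb")))
  g <- list(a = "Mo", b = "Pb")
  expect_error(bkmr_probit(rep(1, 20), Z, groups = g), "separation")
  expect_error(bkmr_probit(rep(c(0, 1), 10), Z,
                           groups = list(a = "Mo")), "partition")
  expect_error(bkmr_probit(rep(c(0, 1), 10), Z,
                           groups = list(a = c("Mo", "Pb"), b = "Pb")),
               "partition")
  expect_error(bkmr_probit(c(rep(0, 10), rep(2, 10)), Z, groups = g),
               "binary")
})

test_that("the printed full schedule retains exactly 5000 draws", {
  # arithmetic of the production schedule, checked through the same
  # bookkeeping the sampler uses
  expect_equal(mcmc_retained(100000, 100000 / 2, 10), 5000)
})

test_that("with the surface disabled the sampler is Bayesian probit regression", {
  set.seed(40)
  n <- 400
  x <- rnorm(n)
  eta <- -0.3 + 0.9 * x
  y <- rbinom(n, 1, pnorm(eta))
  Z <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("Mo", "Pb")))
  groups2 <- list(a = "Mo", b = "Pb")
  fit <- bkmr_probit(y, Z, X = data.frame(x = x), groups = groups2,
                     niter = 2000, burnin = 1000, thin = 2,
                     control = bkmr_control(include_h = FALSE), seed = 41)
  ml <- glm(y ~ x, family = binomial(link = "probit"))
  post_mean <- coef(fit)
  post_sd <- apply(fit$draws$theta, 2, sd)
  expect_lt(abs(post_mean[["intercept"]] - coef(ml)[[1]]),
            2 * post_sd[["intercept"]])
  expect_lt(abs(post_mean[["x"]] - coef(ml)[[2]]), 2 * post_sd[["x"]])

  # flipping every label flips the sign of the intercept
  fitf <- bkmr_probit(1L - y, Z, X = data.frame(x = x), groups = groups2,
                      niter = 2000, burnin = 1000, thin = 2,
                      control = bkmr_control(include_h = FALSE), seed = 41)
  expect_lt(abs(coef(fitf)[["intercept"]] + post_mean[["intercept"]]),
            3 * post_sd[["intercept"]])
})

test_that("selection is conservative when exposures carry no signal", {
  # with a diffuse uniform slab, marginal-likelihood selection pays a
  # Lindley-type penalty for activating a group, so null-data group
  # PIPs sit at or below the 0.5 prior rather than hovering around it
  set.seed(42)
  n <- 150
  Z <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, METALS))
  y <- rbinom(n, 1, 0.4)   # independent of Z
  fit <- bkmr_probit(y, Z, niter = 3000, burnin = 1500, thin = 2, seed = 43)
  p <- compute_pips(fit)
  expect_lt(max(p$groups$pip), 0.5)
})
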