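# Synthetic cohort generator. The generator defines the statistical
# structure the analysis assumes — correlated right-skewed urinary metal
# distributions, specific-gravity dilution, covariates, and BP
# trajectories following the varying-coefficient generative equation —
# so that every downstream stage is testable without cohort data.

# Calibration anchors: per-metal geometric means and log-scale SDs
# (natural log), the latter fit to the p10-p90 spread of a log-normal.
.default_log_gm <- log(c(As = 13.55, Cd = 0.41, Co = 0.48, Mg = 59.6,
                         Mo = 58.15, Pb = 0.82, Sb = 0.05, Se = 19.4))
.default_log_gsd <- c(As = 1.3226, Cd = 0.9356, Co = 1.1258, Mg = 0.8455,
                      Mo = 0.7579, Pb = 0.9563, Sb = 0.6651, Se = 0.7571)
.default_lod <- c(As = 0.03, Cd = 0.001, Co = 0.001, Mg = 0.0012,
                  Mo = 0.03, Pb = 0.003, Sb = 0.002, Se = 0.014)

.default_corr <- function(base = 0.15, cd_pb = 0.45) {
  C <- matrix(base, 8, 8, dimnames = list(METALS, METALS))
  diag(C) <- 1
  C["Cd", "Pb"] <- C["Pb", "Cd"] <- cd_pb
  C
}

# Default mixture surfaces. h1 is J-shaped in standardised log Mo with a
# Mo x Pb product term; its interior minimum sits at z_Mo = argmin_z
# (others at their medians). The quadratic is centred so E[h1] = 0 under
# independent standard-normal exposures, keeping the intercept
# calibration clean. h2 is linear in Mo and Co.
.make_h1 <- function(curv = 2.5, argmin_z, interaction = 1.5) {
  f <- function(Z) {
    curv * ((Z[, "Mo"] - argmin_z)^2 - (1 + argmin_z^2)) +
      interaction * Z[, "Mo"] * Z[, "Pb"]
  }
  attributes(f) <- list(argmin_z = argmin_z, curv = curv,
                        interaction = interaction, form = "j_shaped")
  f
}

.make_h2 <- function(mo = -0.2, co = -0.4) {
  f <- function(Z) mo * Z[, "Mo"] + co * Z[, "Co"]
  attributes(f) <- list(mo = mo, co = co, form = "linear")
  f
}

.zero_h <- function() {
  f <- function(Z) rep(0, nrow(Z))
  attributes(f) <- list(form = "null")
  f
}

# Standardised-scale location of a Mo concentration under the default
# population calibration (log2 centre = log2(GM), scale = gsd/ln 2).
.mo_z <- function(ug_l) {
  (log2(ug_l) - .default_log_gm[["Mo"]] / log(2)) /
    (.default_log_gsd[["Mo"]] / log(2))
}

#' Generative configuration for a synthetic cohort
#'
#' Bundles everything the simulator needs: per-metal log-normal
#' parameters (calibrated by default to the motivating cohort's
#' geometric means and p10-p90 spreads), the log-scale correlation
#' matrix (weak positive defaults with Cd-Pb at 0.45, the strongest
#' pairwise correlation reported for this mixture), the
#' specific-gravity distribution, covariate distributions, and the BP
#' generative equation components (intercept and per-year slope in
#' mmHg, mixture surfaces `h1` / `h2` on the standardised scale,
#' covariate coefficients, random-intercept and residual variances) for
#' systolic and diastolic pressure separately.
#'
#' The default `h1` is J-shaped in molybdenum (interior minimum at
#' `mo_min_ugl` = 60 micrograms/L on the population scale) with a Mo x Pb
#' product term; the default `h2` is linear in Mo and Co. `effects =
#' "null"` zeroes both surfaces, the configuration used by the null
#' coverage checks.
#'
#' @param n_subjects number of mother-child pairs.
#' @param effects `"default"` or `"null"`.
#' @param mo_min_ugl Mo concentration (micrograms/L) at the configured
#'   minimum of the default J-shaped surface.
#' @param corr 8 x 8 log-scale correlation matrix; must be symmetric
#'   positive definite with unit diagonal.
#' @param log_gm,log_gsd per-metal natural-log geometric means and SDs.
#' @param sg_mean,sg_sd,sg_bounds truncated-normal parameters for
#'   urinary specific gravity.
#' @param seed optional RNG seed recorded in the spec and applied by
#'   [simulate_cohort()].
#' @return object of class `truth_spec`.
#' @export
truth_spec <- function(n_subjects = 176,
                       effects = c("default", "null"),
                       mo_min_ugl = 60,
                       corr = .default_corr(),
                       log_gm = .default_log_gm,
                       log_gsd = .default_log_gsd,
                       sg_mean = 1.020, sg_sd = 0.006,
                       sg_bounds = c(1.001, 1.040),
                       seed = NULL) {
  effects <- match.arg(effects)
  stopifnot(length(log_gm) == 8, length(log_gsd) == 8)
  if (any(log_gsd < 0)) stop("log_gsd must be nonnegative")
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-10)) ||
      !isTRUE(all.equal(unname(diag(corr)), rep(1, 8))))
    stop("corr must be symmetric with unit diagonal")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("corr is not positive definite (smallest eigenvalue %.3g)",
                 min(ev)))
  argmin_z <- unname(.mo_z(mo_min_ugl))

  if (effects == "default") {
    sbp <- list(gamma1 = 90.2, gamma2 = 2.27,
                h1_fn = .make_h1(2.5, argmin_z, 1.5),
                h2_fn = .make_h2(-0.1, -0.8),
                beta = c(maternal_age = 0.05, educ_medium = -0.5,
                         educ_high = -1.0, maternal_bmi = 0.1,
                         smoking = 0.5, female = -1.0, height = 0.08),
                sigma_b2 = 25, sigma_e2 = 25)
    dbp <- list(gamma1 = 53.5, gamma2 = 1.12,
                h1_fn = .make_h1(2.5, argmin_z, 1.5),
                h2_fn = .make_h2(-0.2, -0.4),
                beta = c(maternal_age = 0.03, educ_medium = -0.3,
                         educ_high = -0.6, maternal_bmi = 0.05,
                         smoking = 0.3, female = -0.5, height = 0.04),
                sigma_b2 = 15, sigma_e2 = 15)
  } else {
    zero_beta <- c(maternal_age = 0, educ_medium = 0, educ_high = 0,
                   maternal_bmi = 0, smoking = 0, female = 0, height = 0)
    sbp <- list(gamma1 = 90.2, gamma2 = 2.27, h1_fn = .zero_h(),
                h2_fn = .zero_h(), beta = zero_beta,
                sigma_b2 = 25, sigma_e2 = 25)
    dbp <- list(gamma1 = 53.5, gamma2 = 1.12, h1_fn = .zero_h(),
                h2_fn = .zero_h(), beta = zero_beta,
                sigma_b2 = 15, sigma_e2 = 15)
  }
  if (any(c(sbp$sigma_b2, sbp$sigma_e2, dbp$sigma_b2, dbp$sigma_e2) < 0))
    stop("variance components must be nonnegative")

  structure(list(
    n_subjects = n_subjects, metals = METALS,
    log_gm = log_gm, log_gsd = log_gsd, corr = corr,
    sg = list(mean = sg_mean, sd = sg_sd, bounds = sg_bounds),
    covariates = list(
      maternal_age = c(mean = 30.3, sd = 4.2),
      education_prob = c(low = 0.102, medium = 0.511, high = 0.386),
      maternal_bmi = c(mean = 24.0, sd = 4.0),
      smoking_prob = 0.227, female_prob = 0.443,
      visit_age = list(`4` = c(mean = 4.2, sd = 0.2),
                       `6` = c(mean = 6.5, sd = 0.3),
                       `11` = c(mean = 10.9, sd = 0.3)),
      visit_height = list(`4` = c(mean = 104.5, sd = 4.2),
                          `6` = c(mean = 120.0, sd = 4.8),
                          `11` = c(mean = 144.3, sd = 6.3)),
      height_age_slope = 5.5, height_sex_shift = 0.5,
      ets_prob = c(`4` = 0.428, `6` = 0.364, `11` = 0.256)),
    sbp = sbp, dbp = dbp,
    effects = effects, mo_min_ugl = mo_min_ugl,
    mo_min_z = argmin_z, ref_sg = 1.020, seed = seed),
    class = "truth_spec")
}

#' @export
print.truth_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort truth specification (%s effects)\n", x$effects))
  cat(sprintf("  subjects: %d   metals: %s\n", x$n_subjects,
              paste(x$metals, collapse = " ")))
  cat(sprintf("  Cd-Pb log-scale correlation: %.2f\n", x$corr["Cd", "Pb"]))
  if (x$effects == "default")
    cat(sprintf("  J-shaped Mo surface, minimum at %.0f ug/L (z = %.3f)\n",
                x$mo_min_ugl, x$mo_min_z))
  invisible(x)
}

# one-sided rejection sampler for the truncated normal SG distribution
.rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

#' Simulate a urinary metal panel
#'
#' Draws dilution-corrected concentrations from a multivariate
#' log-normal with the configured geometric means, spreads and
#' log-scale correlations, draws urinary specific gravity from a
#' truncated normal, and derives the raw spot-sample concentration as
#' `adjusted * (sg - 1) / (ref_sg - 1)` — the exact inverse of the
#' specific-gravity adjustment, so preprocessing recovers the configured
#' mixture distribution. Below-LOD flags are set from the assay
#' detection limits (essentially only ever antimony at these
#' calibrations).
#'
#' @param spec a [truth_spec()].
#' @param n number of subjects (defaults to `spec$n_subjects`).
#' @return data frame (`metal_panel`) with `subject_id`,
#'   `specific_gravity` and one raw-concentration column per metal;
#'   attributes `lod`, `below_lod` and `adjusted` (the dilution-corrected
#'   concentrations actually drawn).
#' @export
simulate_metals <- function(spec, n = spec$n_subjects) {
  ev <- eigen(spec$corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("corr is not positive definite (smallest eigenvalue %.3g)",
                 min(ev)))
  Lc <- chol(spec$corr)
  Zn <- matrix(rnorm(n * 8), n, 8) %*% Lc        # correlated standard normals
  logA <- sweep(sweep(Zn, 2, spec$log_gsd, "*"), 2, spec$log_gm, "+")
  A <- exp(logA)
  colnames(A) <- spec$metals
  sg <- .rtrunc_norm(n, spec$sg$mean, spec$sg$sd,
                     spec$sg$bounds[1], spec$sg$bounds[2])
  raw <- sweep(A, 1, (sg - 1) / (spec$ref_sg - 1), "*")
  flags <- sweep(raw, 2, .default_lod[spec$metals], "<")
  panel <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                      specific_gravity = sg, raw, check.names = FALSE)
  attr(panel, "lod") <- .default_lod[spec$metals]
  attr(panel, "below_lod") <- flags
  attr(panel, "adjusted") <- A
  panel
}

#' Simulate maternal and child covariates
#'
#' Subject-level maternal covariates (age, 3-level education,
#' pre-pregnancy BMI, smoking) and child sex, plus visit-level exact
#' ages, heights (sex- and age-dependent normal means) and
#' environmental tobacco smoke flags for the three visits at
#' approximately 4, 6 and 11 years.
#'
#' @inheritParams simulate_metals
#' @return list with `subjects` (one row per subject) and `visits`
#'   (one row per subject-visit with `visit`, `age`, `height`, `ets`).
#' @export
simulate_covariates <- function(spec, n = spec$n_subjects) {
  cv <- spec$covariates
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    maternal_age = rnorm(n, cv$maternal_age["mean"], cv$maternal_age["sd"]),
    education = factor(
      sample(names(cv$education_prob), n, TRUE, cv$education_prob),
      levels = c("low", "medium", "high")),
    maternal_bmi = rnorm(n, cv$maternal_bmi["mean"], cv$maternal_bmi["sd"]),
    smoking = rbinom(n, 1, cv$smoking_prob),
    sex = ifelse(rbinom(n, 1, cv$female_prob) == 1, "female", "male"))
  visits <- do.call(rbind, lapply(c("4", "6", "11"), function(v) {
    va <- cv$visit_age[[v]]
    vh <- cv$visit_height[[v]]
    age <- rnorm(n, va["mean"], va["sd"])
    hmean <- vh["mean"] + cv$height_age_slope * (age - va["mean"]) +
      ifelse(subjects$sex == "male", cv$height_sex_shift, -cv$height_sex_shift)
    data.frame(subject_id = subjects$subject_id,
               visit = as.integer(v), age = age,
               height = rnorm(n, hmean, vh["sd"]),
               ets = rbinom(n, 1, cv$ets_prob[[v]]))
  }))
  visits <- visits[order(visits$subject_id, visits$visit), ]
  rownames(visits) <- NULL
  list(subjects = subjects, visits = visits)
}

# Covariate design used by the generative equation (centred internally
# so gamma1/gamma2 set the population mean trajectory).
.truth_design <- function(subjects, visits, cv) {
  sub <- subjects[match(visits$subject_id, subjects$subject_id), ]
  age0 <- vapply(as.character(visits$visit),
                 function(v) cv$visit_age[[v]][["mean"]], numeric(1))
  h0 <- vapply(as.character(visits$visit),
               function(v) cv$visit_height[[v]][["mean"]], numeric(1))
  cbind(maternal_age = sub$maternal_age - cv$maternal_age[["mean"]],
        educ_medium = as.numeric(sub$education == "medium"),
        educ_high = as.numeric(sub$education == "high"),
        maternal_bmi = sub$maternal_bmi - cv$maternal_bmi[["mean"]],
        smoking = sub$smoking,
        female = as.numeric(sub$sex == "female"),
        height = visits$height - h0 - cv$height_age_slope * (visits$age - age0))
}

#' Simulate blood-pressure trajectories
#'
#' Generates visit-level BP from the varying-coefficient generative
#' equation
#' \deqn{y_{ij} = \gamma_1 + \gamma_2 (age_{ij} - 4) + h_1(z_i) +
#'   h_2(z_i)(age_{ij} - 4) + x_{ij}^T \beta + b_i + \epsilon_{ij}}
#' with \eqn{b_i \sim N(0, \sigma_b^2)} and
#' \eqn{\epsilon_{ij} \sim N(0, \sigma_e^2)}, separately for systolic
#' and diastolic pressure. Age is centred at 4 years so `h1` is the
#' baseline (age-4) mixture surface.
#'
#' @param spec a [truth_spec()].
#' @param exposures standardised exposure matrix (`exposure_matrix`),
#'   one row per subject in panel order.
#' @param covariates list from [simulate_covariates()].
#' @return list with `bp` (visits table plus `sbp`, `dbp`) and `oracle`
#'   (per-subject true `h1`/`h2` values for each outcome).
#' @export
simulate_bp <- function(spec, exposures, covariates) {
  visits <- covariates$visits
  subjects <- covariates$subjects
  if (any(!is.finite(visits$age))) {
    i <- which(!is.finite(visits$age))[1]
    stop(sprintf("missing exact age for subject %s, visit %d",
                 visits$subject_id[i], visits$visit[i]))
  }
  Z <- as.matrix(exposures)
  n <- nrow(Z)
  idx <- match(visits$subject_id, subjects$subject_id)
  agec <- visits$age - 4
  X <- .truth_design(subjects, visits, spec$covariates)

  oracle <- data.frame(subject_id = subjects$subject_id)
  out <- visits
  for (oc in c("sbp", "dbp")) {
    pars <- spec[[oc]]
    h1 <- pars$h1_fn(Z)
    h2 <- pars$h2_fn(Z)
    b <- rnorm(n, 0, sqrt(pars$sigma_b2))
    eps <- rnorm(nrow(visits), 0, sqrt(pars$sigma_e2))
    out[[oc]] <- pars$gamma1 + pars$gamma2 * agec +
      h1[idx] + h2[idx] * agec +
      drop(X %*% pars$beta[colnames(X)]) + b[idx] + eps
    oracle[[paste0("h1_", oc)]] <- h1
    oracle[[paste0("h2_", oc)]] <- h2
  }
  list(bp = out, oracle = oracle)
}

#' Simulate a complete synthetic cohort
#'
#' One-shot generator: metal panel, covariates, standardised exposures
#' (through the package's own preprocessing path, without the outlier
#' screen so the stored oracle surfaces line up row-for-row), and BP
#' trajectories, plus the true surface values at each subject's
#' exposures.
#'
#' @param spec a [truth_spec()]; `spec$seed`, when set, makes the cohort
#'   fully reproducible.
#' @return object of class `synthetic_cohort`: list with `panel`,
#'   `subjects`, `visits` (includes `sbp`/`dbp`), `exposures`, `oracle`
#'   and `truth`.
#' @export
simulate_cohort <- function(spec = truth_spec()) {
  if (!inherits(spec, "truth_spec")) stop("spec must be a truth_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  panel <- simulate_metals(spec)
  covs <- simulate_covariates(spec)
  adj <- as.data.frame(attr(panel, "adjusted"))
  em <- log2_standardize(adj, ref_sg = spec$ref_sg)
  rownames(em) <- panel$subject_id
  bp <- simulate_bp(spec, em, covs)
  structure(list(panel = panel, subjects = covs$subjects, visits = bp$bp,
                 exposures = em, oracle = bp$oracle, truth = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d visits (%s effects)\n",
              nrow(x$panel), nrow(x$visits), x$truth$effects))
  cat(sprintf("  mean SBP by visit: %s mmHg\n",
              paste(sprintf("%.1f", tapply(x$visits$sbp, x$visits$visit, mean)),
                    collapse = " / ")))
  invisible(x)
}
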