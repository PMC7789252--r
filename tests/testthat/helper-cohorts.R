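# Shared fixtures, built lazily and memoised so expensive objects are
# created once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# default-truth cohort at the study size
default_cohort <- function() {
  memo("default_cohort", simulate_cohort(truth_spec(seed = 424242)))
}

# a modest shared BVCKMR fit on the default cohort (SBP)
shared_sbp_fit <- function() {
  memo("shared_sbp_fit",
       fit_bvckmr(default_cohort(), "sbp", niter = 1500, burnin = 750,
                  thin = 1, seed = 99))
}

toy_bp_reference <- function() {
  load_bp_reference(system.file("extdata", "toy_bp_reference_synthetic.csv",
                                package = "bvckmr"))
}

toy_growth_reference <- function() {
  load_growth_reference(system.file("extdata",
                                    "toy_growth_reference_synthetic.csv",
                                    package = "bvckmr"))
}

# small helper: exposures as a plain data frame for the smooth fits
exposure_frame <- function(cohort) {
  d <- as.data.frame(unclass(cohort$exposures))
  d$subject_id <- rownames(cohort$exposures)
  v <- cohort$visits
  out <- d[match(v$subject_id, d$subject_id), ]
  out$sbp <- v$sbp
  out$dbp <- v$dbp
  out$age <- v$age
  rownames(out) <- NULL
  out
}
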