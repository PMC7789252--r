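# Cohort table IO and the end-to-end pipeline driver:
# simulate -> preprocess -> fit (BVCKMR for SBP and DBP, probit BKMR for
# elevated BP) -> summaries -> report, with seeds and configuration
# recorded alongside every artifact.

.cohort_schemas <- list(
  panel = c("subject_id", "specific_gravity"),
  subjects = c("subject_id", "maternal_age", "education", "maternal_bmi",
               "smoking", "sex"),
  visits = c("subject_id", "visit", "age", "height", "ets", "sbp", "dbp")
)

.check_schema <- function(df, what) {
  need <- .cohort_schemas[[what]]
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")))
  invisible(df)
}

#' Write cohort tables to CSV
#'
#' One file per table: `metal_panel.csv` (one row per subject, raw
#' concentrations + specific gravity), `covariates.csv` (one row per
#' subject) and `bp.csv` (one row per subject-visit). Extra columns are
#' preserved. The truth configuration and seed, when present, go to
#' `truth_spec.yaml`.
#'
#' @param cohort a [simulate_cohort()] object or compatible list.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(panel = file.path(dir, "metal_panel.csv"),
             subjects = file.path(dir, "covariates.csv"),
             visits = file.path(dir, "bp.csv"))
  write.csv(cohort$panel, paths["panel"], row.names = FALSE)
  write.csv(cohort$subjects, paths["subjects"], row.names = FALSE)
  write.csv(cohort$visits, paths["visits"], row.names = FALSE)
  if (!is.null(cohort$truth)) {
    ts <- cohort$truth
    yaml::write_yaml(list(
      n_subjects = ts$n_subjects, effects = ts$effects,
      mo_min_ugl = ts$mo_min_ugl, seed = ts$seed,
      log_gm = as.list(ts$log_gm), log_gsd = as.list(ts$log_gsd),
      corr = apply(ts$corr, 1, as.list),
      sg = ts$sg), file.path(dir, "truth_spec.yaml"))
    paths <- c(paths, truth = file.path(dir, "truth_spec.yaml"))
  }
  invisible(paths)
}

#' Read cohort tables from CSV
#'
#' Inverse of [write_cohort()] for the three data tables; schemas are
#' validated and extra columns pass through untouched.
#'
#' @param dir directory holding `metal_panel.csv`, `covariates.csv`,
#'   `bp.csv`.
#' @return list with `panel`, `subjects`, `visits`.
#' @export
read_cohort <- function(dir) {
  rd <- function(f, what) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("missing cohort file: %s", p))
    df <- read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    .check_schema(df, what)
  }
  subjects <- rd("covariates.csv", "subjects")
  subjects$education <- factor(subjects$education,
                               levels = c("low", "medium", "high"))
  list(panel = rd("metal_panel.csv", "panel"), subjects = subjects,
       visits = rd("bp.csv", "visits"))
}

#' Pipeline run configuration
#'
#' @param n_subjects cohort size for the simulate stage.
#' @param seed master seed; every stage derives its stream from it.
#' @param niter,burnin,thin MCMC schedule for both samplers.
#' @param outcome_def `"static"` or `"percentile"`.
#' @param reference_path,growth_path reference CSVs for the percentile
#'   outcome definition.
#' @param include_ets adjust for environmental tobacco smoke
#'   (sensitivity covariate set).
#' @param metals metal subset to model (default all eight).
#' @param input_dir read an existing cohort instead of simulating.
#' @param out_dir artifact directory.
#' @export
run_config <- function(n_subjects = 176, seed = 1, niter = 2000,
                       burnin = floor(niter / 2), thin = 1,
                       outcome_def = c("static", "percentile"),
                       reference_path = NULL, growth_path = NULL,
                       include_ets = FALSE, metals = METALS,
                       input_dir = NULL, out_dir = tempfile("bvckmr_run")) {
  outcome_def <- match.arg(outcome_def)
  bad <- setdiff(metals, METALS)
  if (length(bad))
    stop(sprintf("unknown metal name(s) in config: %s",
                 paste(bad, collapse = ", ")))
  if (outcome_def == "percentile" &&
      (is.null(reference_path) || is.null(growth_path)))
    stop("percentile outcome definition needs reference_path and growth_path")
  for (p in c(reference_path, growth_path, input_dir))
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("configured path does not exist: %s", p))
  structure(list(n_subjects = n_subjects, seed = seed, niter = niter,
                 burnin = burnin, thin = thin, outcome_def = outcome_def,
                 reference_path = reference_path, growth_path = growth_path,
                 include_ets = include_ets, metals = metals,
                 input_dir = input_dir, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Plain key-value file with the fields of [run_config()]; unknown keys
#' are rejected before any computation.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  ok <- names(formals(run_config))
  bad <- setdiff(names(vals), ok)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> fit (BVCKMR for SBP and
#' DBP; probit BKMR for elevated BP at the final visit) -> summaries,
#' writing cohort tables, the exposure transform record, exclusion log,
#' fixed-effect and contrast tables, exposure-response curves, the PIP
#' table, trace plots and a JSON run report (seed, configuration,
#' per-stage timing) to `config$out_dir`. Identical configurations give
#' identical numeric outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the fitted models, summaries and the
#'   report.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, started = format(Sys.time()),
                 config = unclass(config)[c("n_subjects", "niter", "burnin",
                                            "thin", "outcome_def",
                                            "include_ets", "metals")],
                 stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    report$stages[[name]] <<- round(proc.time()[["elapsed"]] - ts, 2)
    res
  }

  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, 4)

  cohort <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      tabs <- read_cohort(config$input_dir)
      c(tabs, list(truth = NULL))
    } else {
      simulate_cohort(truth_spec(n_subjects = config$n_subjects,
                                 seed = seeds[1]))
    }
  })
  if (is.null(config$input_dir)) write_cohort(cohort, config$out_dir)

  prep <- stage("preprocess", preprocess_metals(cohort$panel,
                                                metals = config$metals))
  write.csv(prep$exclusions, file.path(config$out_dir, "exclusions.csv"),
            row.names = FALSE)
  tr <- data.frame(metal = colnames(prep$exposures),
                   center = attr(prep$exposures, "center"),
                   scale = attr(prep$exposures, "scale"),
                   ref_sg = attr(prep$exposures, "ref_sg"))
  write.csv(tr, file.path(config$out_dir, "transform.csv"),
            row.names = FALSE)
  # analysis objects aligned to retained subjects
  keep_ids <- rownames(prep$exposures)
  ana <- list(subjects = cohort$subjects[cohort$subjects$subject_id %in% keep_ids, ],
              visits = cohort$visits[cohort$visits$subject_id %in% keep_ids, ],
              exposures = prep$exposures)

  fits <- list()
  contrasts <- list()
  for (oc in c("sbp", "dbp")) {
    fits[[oc]] <- stage(paste0("fit_bvckmr_", oc),
      fit_bvckmr(ana, outcome = oc, include_ets = config$include_ets,
                 niter = config$niter, burnin = config$burnin,
                 thin = config$thin,
                 seed = seeds[if (oc == "sbp") 2 else 3]))
    fx <- summarize_fixed_effects(fits[[oc]])
    write.csv(fx, file.path(config$out_dir,
                            sprintf("fixed_effects_%s.csv", oc)),
              row.names = FALSE)
    for (tg in c("h1", "h2")) {
      con <- do.call(rbind, lapply(colnames(ana$exposures), function(m)
        iqr_contrast(fits[[oc]], m, tg, ndraws = 200)))
      contrasts[[paste(oc, tg, sep = "_")]] <- con
      write.csv(con, file.path(config$out_dir,
                               sprintf("contrasts_%s_%s.csv", oc, tg)),
                row.names = FALSE)
    }
    curve <- exposure_response(fits[[oc]], "Mo", "h1", ndraws = 200)
    write.csv(as.data.frame(curve),
              file.path(config$out_dir, sprintf("curve_Mo_%s.csv", oc)),
              row.names = FALSE)
    plot_traces(fits[[oc]], pars = c("sigma_e2", "sigma_b2", "tau1_2"),
                file_prefix = file.path(config$out_dir,
                                        paste0("trace_", oc)))
  }

  ybin <- stage("outcome", {
    if (config$outcome_def == "static") elevated_bp(ana, "static")
    else elevated_bp(ana, "percentile",
                     reference = load_bp_reference(config$reference_path),
                     growth = load_growth_reference(config$growth_path))
  })
  report$elevated_prevalence <- mean(ybin)

  fits$bkmr <- stage("fit_bkmr", {
    v11 <- ana$visits[ana$visits$visit == 11, ]
    s <- ana$subjects[match(v11$subject_id, ana$subjects$subject_id), ]
    X <- data.frame(maternal_age = s$maternal_age, education = s$education,
                    maternal_bmi = s$maternal_bmi, smoking = s$smoking,
                    sex = factor(s$sex, levels = c("male", "female")),
                    height = v11$height)
    if (config$include_ets) X$ets <- v11$ets
    grp <- Filter(length, lapply(METAL_GROUPS, intersect, config$metals))
    bkmr_probit(ybin[match(v11$subject_id, names(ybin))],
                .subset_exposures(ana$exposures,
                                  match(v11$subject_id,
                                        rownames(ana$exposures))), X,
                groups = grp, niter = config$niter, burnin = config$burnin,
                thin = max(config$thin, 1), seed = seeds[4])
  })
  pips <- compute_pips(fits$bkmr)
  write.csv(pips$metals, file.path(config$out_dir, "pips.csv"),
            row.names = FALSE)
  plot_traces(fits$bkmr, pars = "tau2",
              file_prefix = file.path(config$out_dir, "trace_bkmr"))

  report$finished <- format(Sys.time())
  report$elapsed <- round(proc.time()[["elapsed"]] - t0, 2)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fits = fits, contrasts = contrasts, pips = pips,
                 prevalence = mean(ybin), report = report,
                 out_dir = config$out_dir))
}
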