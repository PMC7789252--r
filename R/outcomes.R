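# Blood-pressure outcome construction: averaging repeated readings and
# classifying elevated BP under the static (Xi et al.-style) and
# percentile-based (AAP-style, user-supplied reference table) cutoffs.

#' Average repeated blood-pressure readings
#'
#' The visit-level BP measure is the arithmetic mean of the (at least
#' three) readings taken one minute apart; fewer than three readings
#' trigger a warning but are still averaged.
#'
#' @param readings matrix or data frame with columns `sbp` and `dbp`
#'   (mmHg), one row per reading.
#' @return named numeric vector `c(sbp_mean, dbp_mean)`.
#' @examples
#' average_readings(data.frame(sbp = c(100, 102, 104), dbp = c(60, 62, 64)))
#' @export
average_readings <- function(readings) {
  readings <- as.data.frame(readings)
  if (nrow(readings) == 0) stop("no readings supplied")
  if (!all(c("sbp", "dbp") %in% colnames(readings)))
    stop("readings need 'sbp' and 'dbp' columns")
  if (nrow(readings) < 3)
    warning(sprintf("only %d reading(s); protocol expects at least 3",
                    nrow(readings)))
  c(sbp_mean = mean(readings$sbp), dbp_mean = mean(readings$dbp))
}

#' Static elevated-BP classification
#'
#' Elevated blood pressure by the static school-age cutoffs: systolic
#' mean `>= 110` mmHg (inclusive) and/or diastolic mean `> 70` mmHg
#' (strict), the definition used for the primary binary outcome at
#' about 11 years of age.
#'
#' @param sbp_mean,dbp_mean visit-mean systolic / diastolic BP (mmHg);
#'   vectorised.
#' @return logical: `TRUE` = elevated.
#' @examples
#' classify_elevated_static(110, 60)  # TRUE  (SBP boundary inclusive)
#' classify_elevated_static(105, 70)  # FALSE (DBP boundary strict)
#' @export
classify_elevated_static <- function(sbp_mean, dbp_mean) {
  if (any(!is.finite(sbp_mean)) || any(!is.finite(dbp_mean)))
    stop("BP means must be finite")
  if (any(sbp_mean < 0) || any(dbp_mean < 0))
    stop("negative blood pressure values")
  sbp_mean >= 110 | dbp_mean > 70
}

#' Read a BP percentile reference table
#'
#' Schema: columns `sex` ("male"/"female"), `age` (years),
#' `height_percentile` (0-100), `sbp_p90`, `dbp_p90` (mmHg) — the 90th
#' BP percentile thresholds by sex, age and height percentile. The
#' package does not embed any normative table; a small synthetic toy
#' reference ships under `inst/extdata/` for tests and examples.
#'
#' @param path CSV file path.
#' @export
load_bp_reference <- function(path) {
  ref <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", "height_percentile", "sbp_p90", "dbp_p90")
  miss <- setdiff(need, colnames(ref))
  if (length(miss))
    stop(sprintf("reference table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  ref
}

#' Read a growth reference for height percentiles
#'
#' Schema: columns `sex`, `age` (years), `height_mean`, `height_sd`
#' (cm); the child's height percentile is the normal quantile of the
#' age/sex-interpolated mean and SD.
#'
#' @param path CSV file path.
#' @export
load_growth_reference <- function(path) {
  ref <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", "height_mean", "height_sd")
  miss <- setdiff(need, colnames(ref))
  if (length(miss))
    stop(sprintf("growth reference missing column(s): %s",
                 paste(miss, collapse = ", ")))
  ref
}

.interp_in_age <- function(ages, values, age) {
  if (age < min(ages) || age > max(ages))
    stop(sprintf("age %.2f outside reference range [%.2f, %.2f]",
                 age, min(ages), max(ages)))
  approx(ages, values, xout = age, ties = mean)$y
}

#' Height percentile from a growth reference
#'
#' @param height height (cm).
#' @param sex "male" or "female".
#' @param age age in years (must fall within the reference's range).
#' @param growth growth reference table ([load_growth_reference()]).
#' @return percentile in (0, 100).
#' @export
height_percentile <- function(height, sex, age, growth) {
  g <- growth[growth$sex == sex, ]
  if (!nrow(g)) stop(sprintf("no growth reference rows for sex '%s'", sex))
  g <- g[order(g$age), ]
  mu <- .interp_in_age(g$age, g$height_mean, age)
  sdv <- .interp_in_age(g$age, g$height_sd, age)
  100 * pnorm((height - mu) / sdv)
}

# bilinear interpolation of a threshold column: first in age, then in
# height percentile
.ref_threshold <- function(ref, sex, age, hpct, col) {
  r <- ref[ref$sex == sex, ]
  if (!nrow(r)) stop(sprintf("no reference rows for sex '%s'", sex))
  ages <- sort(unique(r$age))
  if (age < min(ages) || age > max(ages))
    stop(sprintf("age %.2f outside reference range [%.2f, %.2f]",
                 age, min(ages), max(ages)))
  lo <- max(ages[ages <= age])
  hi <- min(ages[ages >= age])
  val_at_age <- function(a) {
    ra <- r[r$age == a, ]
    ra <- ra[order(ra$height_percentile), ]
    hps <- ra$height_percentile
    if (hpct < min(hps) || hpct > max(hps))
      stop(sprintf("height percentile %.1f outside reference range [%.1f, %.1f]",
                   hpct, min(hps), max(hps)))
    approx(hps, ra[[col]], xout = hpct, ties = mean)$y
  }
  if (lo == hi) return(val_at_age(lo))
  v <- c(val_at_age(lo), val_at_age(hi))
  approx(c(lo, hi), v, xout = age)$y
}

#' Percentile-based elevated-BP classification
#'
#' Elevated BP under percentile cutoffs: systolic or diastolic mean
#' greater than or equal to the 90th-percentile threshold for the
#' child's sex, age and height percentile, with thresholds interpolated
#' linearly between the tabulated rows of a user-supplied reference.
#'
#' @inheritParams classify_elevated_static
#' @param sex "male"/"female" per child.
#' @param age age in years per child.
#' @param height height (cm) per child.
#' @param reference BP reference table ([load_bp_reference()]).
#' @param growth growth reference ([load_growth_reference()]).
#' @return logical vector, `TRUE` = elevated.
#' @export
classify_elevated_percentile <- function(sbp_mean, dbp_mean, sex, age,
                                         height, reference, growth) {
  if (any(!is.finite(sbp_mean)) || any(!is.finite(dbp_mean)))
    stop("BP means must be finite")
  n <- length(sbp_mean)
  out <- logical(n)
  for (i in seq_len(n)) {
    hp <- height_percentile(height[i], sex[i], age[i], growth)
    s90 <- .ref_threshold(reference, sex[i], age[i], hp, "sbp_p90")
    d90 <- .ref_threshold(reference, sex[i], age[i], hp, "dbp_p90")
    out[i] <- sbp_mean[i] >= s90 | dbp_mean[i] >= d90
  }
  out
}

#' Elevated-BP outcome for a cohort's final visit
#'
#' Convenience constructor of the binary outcome analysed by
#' [bkmr_probit()]: classifies the (approximately) 11-year visit of a
#' cohort under the chosen cutoff system.
#'
#' @param cohort a [simulate_cohort()] object or compatible list.
#' @param method `"static"` or `"percentile"`.
#' @param reference,growth reference tables for the percentile method.
#' @return named logical vector (subject ids).
#' @export
elevated_bp <- function(cohort, method = c("static", "percentile"),
                        reference = NULL, growth = NULL) {
  method <- match.arg(method)
  v11 <- cohort$visits[cohort$visits$visit == 11, ]
  out <- if (method == "static") {
    classify_elevated_static(v11$sbp, v11$dbp)
  } else {
    if (is.null(reference) || is.null(growth))
      stop("percentile method needs 'reference' and 'growth' tables")
    sex <- cohort$subjects$sex[match(v11$subject_id,
                                     cohort$subjects$subject_id)]
    classify_elevated_percentile(v11$sbp, v11$dbp, sex, v11$age,
                                 v11$height, reference, growth)
  }
  setNames(out, v11$subject_id)
}
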