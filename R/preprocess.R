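# Raw urinary concentrations -> standardised exposure matrix.
# Fixed pipeline order: LOD policy -> specific-gravity adjustment ->
# outlier exclusion on the log2 scale -> centre/scale.

#' Specific-gravity dilution adjustment
#'
#' Corrects a urinary concentration for urine dilution using the
#' specific-gravity formula
#' `conc * (ref_sg - 1) / (sg - 1)`,
#' with reference specific gravity 1.020 (the assay-panel mean).
#'
#' @param conc positive concentration (any unit); vectorised.
#' @param sg individual urinary specific gravity, `> 1`.
#' @param ref_sg reference specific gravity (default 1.020).
#' @return adjusted concentration in the same units.
#' @examples
#' adjust_specific_gravity(1.0, 1.020)  # 1: sg at the reference
#' adjust_specific_gravity(1.0, 1.010)  # 2: dilute urine scaled up
#' @export
adjust_specific_gravity <- function(conc, sg, ref_sg = 1.020) {
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be positive and finite")
  if (any(!is.finite(sg)) || any(sg <= 1))
    stop("specific gravity must exceed 1 (adjustment formula undefined at sg <= 1)")
  conc * (ref_sg - 1) / (sg - 1)
}

#' Mean +/- k SD outlier screen
#'
#' Flags values lying outside `mean(x) +/- k * sd(x)` (default `k = 4`),
#' with mean and SD taken over all supplied values in a single pass.
#' A zero or non-finite SD (constant input) excludes nothing.
#'
#' @param values numeric vector (typically one metal on the log2
#'   SG-adjusted scale).
#' @param k SD multiplier; `Inf` retains everything.
#' @return logical mask, `TRUE` for retained values, with attribute
#'   `"bounds"` = `c(lower, upper)`.
#' @export
exclude_outliers <- function(values, k = 4) {
  if (sum(is.finite(values)) < 2L)
    stop("need at least two finite values to estimate mean and SD")
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    keep <- rep(TRUE, length(values))
    attr(keep, "bounds") <- c(-Inf, Inf)
    return(keep)
  }
  lo <- m - k * s
  hi <- m + k * s
  keep <- values >= lo & values <= hi
  if (!any(keep)) stop("outlier screen excluded every value; check k")
  attr(keep, "bounds") <- c(lo, hi)
  keep
}

#' Apply a below-LOD policy to a metal panel
#'
#' The default policy, `"retain_machine_value"`, keeps the instrument
#' reading for entries flagged below the limit of detection and only
#' preserves the flag (the treatment used for the single below-LOD
#' antimony sample in the motivating cohort). The `"lod_sqrt2"` policy
#' substitutes `LOD / sqrt(2)`.
#'
#' @param panel a metal panel data frame (see [simulate_metals()]): one
#'   row per subject, metal concentration columns, and optionally
#'   attributes `lod` (named numeric) and `below_lod` (logical matrix).
#' @param policy `"retain_machine_value"` (default) or `"lod_sqrt2"`.
#' @return the panel with the policy applied; flags are preserved.
#' @export
handle_lod <- function(panel, policy = c("retain_machine_value", "lod_sqrt2")) {
  policy <- match.arg(policy)
  flags <- attr(panel, "below_lod")
  if (is.null(flags) || !any(flags)) return(panel)
  if (policy == "retain_machine_value") return(panel)
  lod <- attr(panel, "lod")
  if (is.null(lod)) stop("substitution policy requires an 'lod' attribute")
  for (m in colnames(flags)) {
    idx <- which(flags[, m])
    if (!length(idx)) next
    if (is.na(lod[[m]]))
      stop(sprintf("below-LOD entries for %s but no LOD value recorded", m))
    panel[idx, m] <- lod[[m]] / sqrt(2)
  }
  panel
}

#' Log2-transform and standardise an adjusted metal panel
#'
#' Per metal: take log2, subtract the column mean, divide by the column
#' SD (n - 1 denominator). The centring and scaling constants are stored
#' so any standardised value can be mapped back to original
#' (SG-adjusted) units.
#'
#' @param x data frame or matrix of positive SG-adjusted concentrations,
#'   one column per metal.
#' @param ref_sg the reference specific gravity recorded in the
#'   transform metadata.
#' @return an `exposure_matrix`: numeric matrix with attributes
#'   `center`, `scale` (log2-scale constants per metal) and `ref_sg`.
#' @seealso [unstandardize()] for the inverse map.
#' @export
log2_standardize <- function(x, ref_sg = 1.020) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  bad <- which(!is.finite(X) | X <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive concentration at row %d, metal %s",
                 bad[1, 1], colnames(X)[bad[1, 2]]))
  }
  L <- log2(X)
  ctr <- colMeans(L)
  scl <- apply(L, 2, sd)
  if (any(scl == 0)) stop("constant metal column; cannot standardise")
  Zs <- sweep(sweep(L, 2, ctr), 2, scl, "/")
  structure(Zs, center = ctr, scale = scl, ref_sg = ref_sg,
            class = c("exposure_matrix", "matrix", "array"))
}

#' Map standardised values back to original units
#'
#' Inverse of the [log2_standardize()] transform:
#' `conc = 2^(z * scale + center)`, in SG-adjusted original units
#' (micrograms per litre; milligrams per litre for Mg).
#'
#' @param em an `exposure_matrix` (or any object carrying `center` and
#'   `scale` attributes).
#' @param z standardised value(s).
#' @param metal metal name selecting the transform record.
#' @export
unstandardize <- function(em, z, metal) {
  ctr <- attr(em, "center")
  scl <- attr(em, "scale")
  if (is.null(ctr) || is.null(scl)) stop("no transform metadata on this object")
  if (!metal %in% names(ctr)) stop(sprintf("unknown metal '%s'", metal))
  2^(z * scl[[metal]] + ctr[[metal]])
}

#' Standardise original-unit concentrations with a stored transform
#'
#' Forward companion of [unstandardize()]: maps SG-adjusted
#' concentrations onto the standardised scale of an existing
#' `exposure_matrix`.
#'
#' @inheritParams unstandardize
#' @param conc positive concentration(s) in SG-adjusted original units.
#' @export
standardize_conc <- function(em, conc, metal) {
  ctr <- attr(em, "center")
  scl <- attr(em, "scale")
  if (is.null(ctr) || is.null(scl)) stop("no transform metadata on this object")
  if (!metal %in% names(ctr)) stop(sprintf("unknown metal '%s'", metal))
  (log2(conc) - ctr[[metal]]) / scl[[metal]]
}

#' Full preprocessing pipeline for a metal panel
#'
#' Applies, in fixed order: the below-LOD policy, specific-gravity
#' adjustment, mean +/- k SD outlier exclusion on the log2 SG-adjusted
#' scale (listwise: a subject outlying for any metal is dropped), and
#' log2 centring/scaling of the retained rows.
#'
#' @param panel metal panel: data frame with `subject_id`,
#'   `specific_gravity` and one column per metal.
#' @param metals metal columns to use (default the intersection of
#'   [METALS] with the panel's columns).
#' @param ref_sg reference specific gravity.
#' @param lod_policy see [handle_lod()].
#' @param outlier_k SD multiplier for the outlier screen
#'   (`Inf` disables it).
#' @param outlier_scale `"log2"` (default) applies the screen on the
#'   log2 SG-adjusted scale; `"raw"` on SG-adjusted concentrations.
#' @return list with `exposures` (the `exposure_matrix` for retained
#'   subjects, rownames = subject ids), `adjusted` (SG-adjusted panel),
#'   `exclusions` (data frame logging each excluded subject with the
#'   offending metal, value and bounds), `retained` (logical mask over
#'   input rows), and `steps` (the pipeline stages applied, in order).
#' @export
preprocess_metals <- function(panel, metals = NULL, ref_sg = 1.020,
                              lod_policy = "retain_machine_value",
                              outlier_k = 4, outlier_scale = c("log2", "raw")) {
  outlier_scale <- match.arg(outlier_scale)
  if (is.null(metals)) metals <- intersect(METALS, colnames(panel))
  if (!length(metals)) stop("no metal columns found in panel")
  miss <- setdiff(c("subject_id", "specific_gravity"), colnames(panel))
  if (length(miss))
    stop(sprintf("panel is missing required column(s): %s",
                 paste(miss, collapse = ", ")))

  panel <- handle_lod(panel, lod_policy)
  adj <- panel
  for (m in metals)
    adj[[m]] <- adjust_specific_gravity(panel[[m]], panel$specific_gravity,
                                        ref_sg)

  screen_vals <- as.matrix(adj[metals])
  if (outlier_scale == "log2") screen_vals <- log2(screen_vals)
  keep <- rep(TRUE, nrow(adj))
  logs <- list()
  if (is.finite(outlier_k)) {
    for (m in metals) {
      km <- exclude_outliers(screen_vals[, m], k = outlier_k)
      out <- which(!km)
      if (length(out)) {
        bounds <- attr(km, "bounds")
        logs[[m]] <- data.frame(
          subject_id = adj$subject_id[out], metal = m,
          value = screen_vals[out, m],
          lower = bounds[1], upper = bounds[2])
      }
      keep <- keep & km
    }
  }
  if (!any(keep)) stop("outlier screen excluded every subject")
  exclusions <- if (length(logs)) do.call(rbind, c(logs, make.row.names = FALSE))
                else data.frame(subject_id = character(), metal = character(),
                                value = numeric(), lower = numeric(),
                                upper = numeric())

  em <- log2_standardize(adj[keep, metals, drop = FALSE], ref_sg = ref_sg)
  rownames(em) <- as.character(adj$subject_id[keep])
  list(exposures = em, adjusted = adj, exclusions = exclusions,
       retained = keep,
       steps = c(sprintf("lod_policy:%s", lod_policy),
                 sprintf("sg_adjust:ref=%.3f", ref_sg),
                 sprintf("outlier_screen:%s,k=%g", outlier_scale, outlier_k),
                 "log2_standardize:sd=n-1"))
}
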