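# Confirmatory single-metal smooth fits: penalised cubic-spline
# (P-spline) smooths with linear covariate adjustment, a subject
# random intercept for the longitudinal BP measures, and tensor-product
# interaction surfaces for metal pairs. Backed by mgcv.

#' Single-metal penalised-spline fit
#'
#' The confirmatory counterpart of the mixture models: one metal at a
#' time, a cubic P-spline smooth (10 basis functions, second-difference
#' penalty, smoothing parameter by GCV) plus linear covariates, and —
#' for longitudinal outcomes — a subject random intercept through the
#' mixed-model representation of an `mgcv` random-effect smooth.
#'
#' @param data data frame with the outcome, a standardised exposure
#'   column per metal, covariates, and (for longitudinal fits) a
#'   `subject_id` column.
#' @param metal exposure column to smooth.
#' @param outcome outcome column name.
#' @param covariates covariate column names entering linearly.
#' @param longitudinal add the subject random intercept.
#' @param k spline basis dimension (default 10).
#' @param sp optional fixed smoothing parameter for the metal smooth
#'   (e.g. very large to force linearity); `NULL` selects by GCV.
#' @param grid_size evaluation grid size for the fitted curve.
#' @return object of class `metal_gamm`: list with the `mgcv::gam` fit
#'   (`model`), `edf` of the metal smooth, and `curve` (grid data frame
#'   with the smooth's centred contribution).
#' @export
fit_metal_gamm <- function(data, metal, outcome, covariates = character(0),
                           longitudinal = FALSE, k = 10, sp = NULL,
                           grid_size = 50) {
  if (!metal %in% colnames(data)) stop(sprintf("unknown metal '%s'", metal))
  if (nrow(data) <= k)
    stop(sprintf("need more rows (%d) than basis functions (%d)",
                 nrow(data), k))
  rhs <- sprintf("s(%s, bs = 'ps', k = %d, m = c(2, 2))", metal, k)
  if (length(covariates))
    rhs <- paste(c(rhs, covariates), collapse = " + ")
  spv <- if (is.null(sp)) NULL else sp[1]
  if (longitudinal) {
    if (!"subject_id" %in% colnames(data))
      stop("longitudinal fit needs a 'subject_id' column")
    data$subject_id <- factor(data$subject_id)
    rhs <- paste(rhs, "+ s(subject_id, bs = 're')")
    if (!is.null(spv)) spv <- c(spv, -1)  # -1 = estimate the re smooth
  }
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- mgcv::gam(fml, data = data, method = "GCV.Cp", sp = spv)
  grid <- seq(quantile(data[[metal]], 0.01), quantile(data[[metal]], 0.99),
              length.out = grid_size)
  nd <- data[rep(1, grid_size), , drop = FALSE]
  nd[[metal]] <- grid
  terms <- predict(fit, newdata = nd, type = "terms")
  smooth_col <- grep(sprintf("s\\(%s\\)", metal), colnames(terms))
  curve <- data.frame(z = grid, fit = terms[, smooth_col])
  edf <- sum(fit$edf[fit$smooth[[1]]$first.para:fit$smooth[[1]]$last.para])
  structure(list(model = fit, metal = metal, outcome = outcome,
                 edf = edf, curve = curve, longitudinal = longitudinal),
            class = "metal_gamm")
}

#' @export
print.metal_gamm <- function(x, ...) {
  cat(sprintf("Penalised-spline fit: %s ~ s(%s)%s\n", x$outcome, x$metal,
              if (x$longitudinal) " + subject random intercept" else ""))
  cat(sprintf("  effective degrees of freedom of the smooth: %.2f\n", x$edf))
  invisible(x)
}

#' Pairwise-interaction penalised surface
#'
#' Main-effect smooths for two metals plus a tensor-product interaction
#' smooth (`ti`), linear covariates, and optionally the subject random
#' intercept. Reports the interaction component's share of the total
#' smooth variance and a finite-difference cross-difference of the
#' fitted surface at the exposure quartiles, whose sign tracks the sign
#' of a product interaction.
#'
#' @inheritParams fit_metal_gamm
#' @param metal1,metal2 the two exposure columns (must differ).
#' @param k_main,k_int basis dimensions of the main-effect / interaction
#'   smooths.
#' @return object of class `metal_interaction`: the fit, a 2-D `grid`
#'   of surface values, `interaction_share`, and `cross_difference`.
#' @export
fit_metal_interaction <- function(data, metal1, metal2, outcome,
                                  covariates = character(0),
                                  longitudinal = FALSE, k_main = 8,
                                  k_int = 5, grid_size = 20) {
  if (identical(metal1, metal2)) stop("metal1 and metal2 must differ")
  rhs <- sprintf(
    "s(%s, bs = 'ps', k = %d) + s(%s, bs = 'ps', k = %d) + ti(%s, %s, bs = 'ps', k = %d)",
    metal1, k_main, metal2, k_main, metal1, metal2, k_int)
  if (length(covariates)) rhs <- paste(c(rhs, covariates), collapse = " + ")
  if (longitudinal) {
    data$subject_id <- factor(data$subject_id)
    rhs <- paste(rhs, "+ s(subject_id, bs = 're')")
  }
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- mgcv::gam(fml, data = data, method = "GCV.Cp")

  terms <- predict(fit, type = "terms")
  cn <- colnames(terms)
  main_cols <- grep(sprintf("^s\\((%s|%s)\\)$", metal1, metal2), cn)
  ti_col <- grep("^ti\\(", cn)
  tot <- rowSums(terms[, c(main_cols, ti_col), drop = FALSE])
  share <- if (var(tot) > 0) var(terms[, ti_col]) / var(tot) else 0

  g1 <- seq(quantile(data[[metal1]], 0.05), quantile(data[[metal1]], 0.95),
            length.out = grid_size)
  g2 <- seq(quantile(data[[metal2]], 0.05), quantile(data[[metal2]], 0.95),
            length.out = grid_size)
  gg <- expand.grid(a = g1, b = g2)
  nd <- data[rep(1, nrow(gg)), , drop = FALSE]
  nd[[metal1]] <- gg$a
  nd[[metal2]] <- gg$b
  tg <- predict(fit, newdata = nd, type = "terms")
  surf <- matrix(rowSums(tg[, c(grep(sprintf("^s\\((%s|%s)\\)$", metal1, metal2),
                                     colnames(tg)),
                                grep("^ti\\(", colnames(tg))), drop = FALSE]),
                 grid_size, grid_size)

  q1 <- quantile(data[[metal1]], c(0.25, 0.75))
  q2 <- quantile(data[[metal2]], c(0.25, 0.75))
  corner <- function(a, b) {
    nd1 <- data[1, , drop = FALSE]
    nd1[[metal1]] <- a
    nd1[[metal2]] <- b
    tt <- predict(fit, newdata = nd1, type = "terms")
    sum(tt[, c(main_cols, ti_col)])
  }
  cd <- corner(q1[2], q2[2]) - corner(q1[2], q2[1]) -
        corner(q1[1], q2[2]) + corner(q1[1], q2[1])

  structure(list(model = fit, metal1 = metal1, metal2 = metal2,
                 outcome = outcome, grid = list(z1 = g1, z2 = g2,
                                                surface = surf),
                 interaction_share = share, cross_difference = cd),
            class = "metal_interaction")
}

#' @export
print.metal_interaction <- function(x, ...) {
  cat(sprintf("Tensor-product interaction surface: %s ~ %s x %s\n",
              x$outcome, x$metal1, x$metal2))
  cat(sprintf("  interaction share of smooth variance: %.3f\n",
              x$interaction_share))
  cat(sprintf("  quartile cross-difference: %.3f\n", x$cross_difference))
  invisible(x)
}
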