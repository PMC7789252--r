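# Posterior draws -> reported quantities: interquartile-range contrasts,
# univariate exposure-response curves, bivariate interaction surfaces,
# inflection points, and the descriptive metal correlation matrix.

# conditioning profile: chosen metal at given standardised values,
# every other metal at its observed quantile (default median)
.profile_points <- function(Z, metal, zvals, fixed_q = 0.5,
                            fixed = NULL) {
  metals <- colnames(Z)
  if (!metal %in% metals) stop(sprintf("unknown metal '%s'", metal))
  base <- apply(Z, 2, quantile, probs = fixed_q)
  if (!is.null(fixed)) base[names(fixed)] <- fixed
  out <- matrix(rep(base, each = length(zvals)), length(zvals),
                dimnames = list(NULL, metals))
  out[, metal] <- zvals
  out
}

#' Interquartile-range contrast for one mixture component
#'
#' The relative-importance measure: the change in the fitted surface
#' when the chosen metal moves from its 25th to its 75th observed
#' percentile while every other metal is held at its median. Computed
#' per retained draw (surface extended to the two profiles by GP
#' conditioning under that draw's kernel weights) and summarised as the
#' posterior mean with an equal-tailed 95% credible interval.
#'
#' @param fit a [bvckmr()] or [bkmr_probit()] fit.
#' @param metal metal name.
#' @param target `"h1"` (baseline surface, mmHg), `"h2"` (per-year
#'   surface, mmHg/yr) or `"h"` (binary fit, latent probit scale).
#' @param probs contrast quantiles, default `c(0.25, 0.75)`.
#' @param level credible level.
#' @param ndraws,method see [predict.bvckmr()].
#' @return one-row data frame: `metal`, `target`, `estimate`, `lower`,
#'   `upper`, `significant`.
#' @export
iqr_contrast <- function(fit, metal, target = c("h1", "h2", "h"),
                         probs = c(0.25, 0.75), level = 0.95,
                         ndraws = NULL, method = "draws") {
  target <- match.arg(target)
  Z <- as.matrix(fit$Z)
  zq <- quantile(Z[, metal], probs = probs)
  P <- .profile_points(Z, metal, zq)
  hd <- .predict_surface(fit, P, target, ndraws, method)
  d <- hd[, 2] - hd[, 1]
  a <- (1 - level) / 2
  ci <- quantile(d, c(a, 1 - a))
  data.frame(metal = metal, target = target, estimate = mean(d),
             lower = unname(ci[1]), upper = unname(ci[2]),
             significant = ci[1] > 0 | ci[2] < 0, row.names = NULL)
}

#' Univariate exposure-response curve
#'
#' Posterior mean and pointwise credible band of the fitted surface
#' along one metal, over an equally spaced grid spanning the metal's
#' observed 1st-99th percentile on the standardised scale, with the
#' other metals fixed at their medians (or another quantile). The grid
#' is also reported in original (SG-adjusted) concentration units via
#' the exposure matrix's transform record, when available.
#'
#' @inheritParams iqr_contrast
#' @param grid_size number of grid points (default 50).
#' @param grid optional explicit standardised grid (a warning is
#'   recorded on the curve when it extends beyond the observed support).
#' @param fixed_q quantile at which the other metals are held.
#' @param fixed named vector of standardised values overriding
#'   `fixed_q` for specific metals.
#' @return object of class `exposure_response`: data frame with `z`
#'   (standardised), `conc` (original units, `NA` without transform
#'   metadata), `mean`, `lower`, `upper`; attributes `metal`, `target`,
#'   `conditioning`, `warnings`.
#' @export
exposure_response <- function(fit, metal, target = c("h1", "h2", "h"),
                              grid_size = 50, grid = NULL, fixed_q = 0.5,
                              fixed = NULL, level = 0.95, ndraws = NULL,
                              method = "draws") {
  target <- match.arg(target)
  Z <- as.matrix(fit$Z)
  if (!metal %in% colnames(Z)) stop(sprintf("unknown metal '%s'", metal))
  sup <- quantile(Z[, metal], c(0.01, 0.99))
  warn <- character(0)
  if (is.null(grid)) {
    grid <- seq(sup[1], sup[2], length.out = grid_size)
  } else {
    if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
    if (min(grid) < min(Z[, metal]) || max(grid) > max(Z[, metal]))
      warn <- "grid extends beyond the observed exposure support"
  }
  P <- .profile_points(Z, metal, grid, fixed_q, fixed)
  hd <- .predict_surface(fit, P, target, ndraws, method)
  if (any(!is.finite(hd))) stop("non-finite fitted curve values")
  a <- (1 - level) / 2
  conc <- tryCatch(unstandardize(fit$Z, grid, metal),
                   error = function(e) rep(NA_real_, length(grid)))
  out <- data.frame(z = grid, conc = conc, mean = colMeans(hd),
                    lower = apply(hd, 2, quantile, a),
                    upper = apply(hd, 2, quantile, 1 - a))
  structure(out, metal = metal, target = target,
            conditioning = list(fixed_q = fixed_q, fixed = fixed),
            warnings = warn,
            class = c("exposure_response", "data.frame"))
}

#' @export
plot.exposure_response <- function(x, xunit = c("z", "conc"), ...) {
  xunit <- match.arg(xunit)
  xv <- x[[xunit]]
  graphics::plot(xv, x$mean, type = "n", ylim = range(x$lower, x$upper),
                 xlab = if (xunit == "z") "standardised exposure"
                        else "concentration (original units)",
                 ylab = paste0(attr(x, "target"), "(z)"),
                 main = attr(x, "metal"), ...)
  graphics::polygon(c(xv, rev(xv)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(xv, x$mean, lwd = 2)
  invisible(x)
}

#' Bivariate exposure-response surfaces
#'
#' The first metal's exposure-response curve computed with the second
#' metal pinned at each requested quantile (remaining metals at their
#' medians) — parallel curves indicate additivity, diverging curves an
#' interaction. Defaults follow the reporting convention: 25th/75th
#' percentiles of the second metal for longitudinal fits, 10th/50th/90th
#' for binary fits.
#'
#' @inheritParams exposure_response
#' @param metal1 metal on the curve axis.
#' @param metal2 conditioning metal (must differ from `metal1`).
#' @param quantiles quantiles of `metal2`; default depends on fit class.
#' @return named list of [exposure_response()] curves, one per
#'   `metal2` quantile, class `bivariate_surface`.
#' @export
bivariate_surface <- function(fit, metal1, metal2, quantiles = NULL,
                              target = c("h1", "h2", "h"), grid_size = 50,
                              level = 0.95, ndraws = NULL,
                              method = "draws") {
  target <- match.arg(target)
  if (identical(metal1, metal2)) stop("metal1 and metal2 must differ")
  if (is.null(quantiles))
    quantiles <- if (inherits(fit, "bkmr_probit")) c(0.1, 0.5, 0.9)
                 else c(0.25, 0.75)
  Z <- as.matrix(fit$Z)
  out <- lapply(quantiles, function(q) {
    z2 <- quantile(Z[, metal2], q)
    exposure_response(fit, metal1, target, grid_size = grid_size,
                      fixed = setNames(z2, metal2), level = level,
                      ndraws = ndraws, method = method)
  })
  names(out) <- sprintf("%s_p%02.0f", metal2, 100 * quantiles)
  structure(out, metal1 = metal1, metal2 = metal2, quantiles = quantiles,
            class = "bivariate_surface")
}

#' @export
plot.bivariate_surface <- function(x, xunit = "z", ...) {
  cols <- c("firebrick", "forestgreen", "steelblue", "orange")
  rng <- range(vapply(x, function(cu) range(cu$mean), numeric(2)))
  first <- x[[1]]
  graphics::plot(first[[xunit]], first$mean, type = "n", ylim = rng,
                 xlab = "standardised exposure", ylab = "h",
                 main = sprintf("%s by %s", attr(x, "metal1"),
                                attr(x, "metal2")), ...)
  for (i in seq_along(x))
    graphics::lines(x[[i]][[xunit]], x[[i]]$mean, col = cols[i], lwd = 2)
  graphics::legend("topleft", legend = names(x), col = cols[seq_along(x)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Posterior cross-difference (interaction check) for two metals
#'
#' Finite-difference interaction measure on the fitted surface:
#' `h(hi,hi) - h(hi,lo) - h(lo,hi) + h(lo,lo)` with the two metals at
#' their 25th/75th percentiles and the rest at medians, summarised over
#' posterior draws. Zero under an additive surface; the sign matches
#' the sign of a product-term interaction.
#'
#' @inheritParams bivariate_surface
#' @param probs low/high quantiles, default `c(0.25, 0.75)`.
#' @return one-row data frame with `estimate`, `lower`, `upper`,
#'   `significant`.
#' @export
cross_difference <- function(fit, metal1, metal2, target = c("h1", "h2", "h"),
                             probs = c(0.25, 0.75), level = 0.95,
                             ndraws = NULL, method = "draws") {
  target <- match.arg(target)
  if (identical(metal1, metal2)) stop("metal1 and metal2 must differ")
  Z <- as.matrix(fit$Z)
  q1 <- quantile(Z[, metal1], probs)
  q2 <- quantile(Z[, metal2], probs)
  med <- apply(Z, 2, median)
  P <- rbind(med, med, med, med)
  colnames(P) <- colnames(Z)
  P[, metal1] <- c(q1[2], q1[2], q1[1], q1[1])
  P[, metal2] <- c(q2[2], q2[1], q2[2], q2[1])
  hd <- .predict_surface(fit, P, target, ndraws, method)
  d <- hd[, 1] - hd[, 2] - hd[, 3] + hd[, 4]
  a <- (1 - level) / 2
  ci <- quantile(d, c(a, 1 - a))
  data.frame(metal1 = metal1, metal2 = metal2, target = target,
             estimate = mean(d), lower = unname(ci[1]),
             upper = unname(ci[2]),
             significant = ci[1] > 0 | ci[2] < 0, row.names = NULL)
}

#' Interior minimum (inflection point) of an exposure-response curve
#'
#' Locates the interior minimum of the posterior-mean curve — the
#' concentration below which the association runs opposite to the
#' association above it, the "inflection point" of a J-shaped
#' relationship. A curve monotone over its grid has none.
#'
#' @param curve an [exposure_response()] object with at least 10 grid
#'   points.
#' @return the exposure value at the minimum in original (SG-adjusted)
#'   concentration units (standardised value as attribute `"z"`), or
#'   `NA` if the curve is monotone.
#' @export
find_inflection <- function(curve) {
  if (nrow(curve) < 10) stop("curve needs at least 10 grid points")
  m <- curve$mean
  if (any(!is.finite(m))) stop("non-finite curve values")
  d <- diff(m)
  if (all(d >= 0) || all(d <= 0)) return(NA_real_)
  interior <- 2:(nrow(curve) - 1)
  i <- interior[which.min(m[interior])]
  # require a genuine sign change around the minimum
  if (!(m[i] <= m[i - 1] && m[i] <= m[i + 1])) return(NA_real_)
  structure(curve$conc[i], z = curve$z[i])
}

#' Pairwise Pearson correlations between metals
#'
#' Descriptive correlation matrix of the standardised exposures, with
#' two-sided p-values. Constant columns give `NA` entries.
#'
#' @param exposures exposure matrix (or any numeric matrix/data frame
#'   with metals in columns), at least 3 rows.
#' @return object of class `metal_correlations`: list with `r`
#'   (correlations, unit diagonal) and `p` (p-values).
#' @export
metal_correlations <- function(exposures) {
  X <- as.matrix(exposures)
  if (nrow(X) < 3) stop("need at least 3 rows")
  M <- ncol(X)
  r <- diag(1, M)
  p <- matrix(NA_real_, M, M)
  dimnames(r) <- dimnames(p) <- list(colnames(X), colnames(X))
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      if (sd(X[, i]) == 0 || sd(X[, j]) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      ct <- cor.test(X[, i], X[, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p), class = "metal_correlations")
}

#' @export
print.metal_correlations <- function(x, digits = 2, ...) {
  cat("Pearson correlations (standardised log2 exposures):\n")
  print(round(x$r, digits))
  invisible(x)
}
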