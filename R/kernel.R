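# Shared Gaussian-kernel and Gaussian-process machinery used by both
# samplers and by the posterior summaries.

#' Component-weighted Gaussian kernel
#'
#' Computes the squared-exponential kernel
#' \deqn{K[a, b] = \exp\{-\sum_m r_m (z_{am} - z'_{bm})^2\}}
#' between the rows of two exposure matrices. The per-component weights
#' `r` act as inverse squared length-scales: a component with `r_m = 0`
#' drops out of the kernel entirely, which is how spike-and-slab
#' selection switches metals off.
#'
#' @param Z numeric matrix (rows = observations, columns = mixture
#'   components), typically a standardised exposure matrix.
#' @param Z2 second matrix with the same columns, or `NULL` for
#'   `K(Z, Z)`. `K(Z, Z)` has unit diagonal.
#' @param r nonnegative numeric vector of component weights, recycled to
#'   the number of columns if scalar.
#' @return `nrow(Z)` x `nrow(Z2)` kernel matrix.
#' @examples
#' Z <- matrix(rnorm(20), 10, 2)
#' K <- gaussian_kernel(Z, r = c(0.5, 0.5))
#' all(diag(K) == 1)
#' @export
gaussian_kernel <- function(Z, Z2 = NULL, r) {
  Z <- as.matrix(Z)
  if (is.null(Z2)) Z2 <- Z else Z2 <- as.matrix(Z2)
  if (ncol(Z) != ncol(Z2))
    stop("Z and Z2 must have the same number of columns")
  if (length(r) == 1L) r <- rep(r, ncol(Z))
  if (length(r) != ncol(Z))
    stop("length of r must match the number of columns")
  if (any(r < 0)) stop("kernel weights r must be nonnegative")
  D <- matrix(0, nrow(Z), nrow(Z2))
  for (m in which(r > 0)) {
    D <- D + r[m] * outer(Z[, m], Z2[, m], function(a, b) (a - b)^2)
  }
  exp(-D)
}

# Cholesky with jitter escalation: start at 1e-8 * trace(K)/n, multiply
# by 10 at most 3 times. Returns list(R = upper Cholesky, jitter).
chol_jitter <- function(K, max_tries = 4L) {
  n <- nrow(K)
  j <- 1e-8 * sum(diag(K)) / n
  for (t in seq_len(max_tries)) {
    R <- tryCatch(chol(K + diag(j, n)), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = j))
    j <- j * 10
  }
  stop(sprintf(
    "Cholesky factorisation failed after jitter escalation (condition estimate %.3g)",
    kappa(K, exact = FALSE)))
}

#' Gaussian-process conditional given noisy observations
#'
#' Standard GP algebra for a surface \eqn{h \sim N(0, \tau^2 K)} observed
#' through \eqn{y = h + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2 I)}:
#' \deqn{E[h \mid y] = \tau^2 K (\tau^2 K + \sigma^2 I)^{-1} y}
#' \deqn{Cov[h \mid y] = \tau^2 K - \tau^2 K (\tau^2 K + \sigma^2 I)^{-1} \tau^2 K}
#' solved through a jitter-stabilised Cholesky factorisation.
#'
#' @param K positive semi-definite kernel matrix.
#' @param y residual vector the surface is conditioned on.
#' @param tau2 GP scale (variance), `> 0`.
#' @param sigma2 observation noise variance, `> 0`.
#' @return object of class `gp_posterior`: list with `mean`, `cov` and
#'   the conditioning inputs.
#' @export
gp_conditional <- function(K, y, tau2, sigma2) {
  K <- as.matrix(K)
  if (!isTRUE(all.equal(K, t(K), tolerance = 1e-8)))
    stop("K must be symmetric")
  if (tau2 <= 0 || sigma2 <= 0) stop("tau2 and sigma2 must be positive")
  if (length(y) != nrow(K)) stop("length(y) must match nrow(K)")
  tK <- tau2 * K
  cf <- chol_jitter(tK + diag(sigma2, nrow(K)))
  Ainv_tK <- chol2inv(cf$R) %*% tK      # (tau2 K + sigma2 I)^{-1} tau2 K
  m <- drop(crossprod(Ainv_tK, y))      # symmetric, so t() %*% y == %*% y
  V <- tK - tK %*% Ainv_tK
  V <- (V + t(V)) / 2
  structure(list(mean = m, cov = V, tau2 = tau2, sigma2 = sigma2, y = y),
            class = "gp_posterior")
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat("Gaussian-process conditional posterior\n")
  cat(sprintf("  points: %d   tau2: %.4g   sigma2: %.4g\n",
              length(x$mean), x$tau2, x$sigma2))
  invisible(x)
}
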