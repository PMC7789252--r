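# Draws-file serialization for fitted models: one CSV per draw matrix
# plus a JSON metadata file (schedule, seed, dimensions, class).

#' Write a fit's posterior draws to disk
#'
#' Serialises every retained draw matrix/vector of a [bvckmr()] or
#' [bkmr_probit()] fit as CSV (`draws_<name>.csv`, one row per retained
#' draw) together with `fit_metadata.json` recording the model class,
#' MCMC schedule, seed and dimensions.
#'
#' @param fit a `bvckmr` or `bkmr_probit` fit.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @seealso [read_fit_draws()]
#' @export
write_fit_draws <- function(fit, dir) {
  if (!inherits(fit, c("bvckmr", "bkmr_probit")))
    stop("fit must be a bvckmr or bkmr_probit object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(fit$draws)) {
    d <- fit$draws[[nm]]
    if (is.null(dim(d))) d <- matrix(d, ncol = 1, dimnames = list(NULL, nm))
    p <- file.path(dir, sprintf("draws_%s.csv", nm))
    write.csv(as.data.frame(d), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(class = class(fit)[1], schedule = fit$schedule,
               n = fit$n, draws = nrow(fit$draws[[1]]),
               components = names(fit$draws))
  mp <- file.path(dir, "fit_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}

#' Read serialized posterior draws
#'
#' Inverse of [write_fit_draws()]: returns the draw matrices and the
#' metadata. This restores the numerical content of a fit (for
#' archiving or external post-processing), not the full fitted object.
#'
#' @param dir directory written by [write_fit_draws()].
#' @return list with `draws` (named list of matrices) and `metadata`.
#' @export
read_fit_draws <- function(dir) {
  mp <- file.path(dir, "fit_metadata.json")
  if (!file.exists(mp)) stop(sprintf("missing metadata file: %s", mp))
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  draws <- list()
  for (nm in meta$components) {
    p <- file.path(dir, sprintf("draws_%s.csv", nm))
    if (!file.exists(p)) stop(sprintf("missing draws file: %s", p))
    draws[[nm]] <- as.matrix(read.csv(p, check.names = FALSE))
  }
  list(draws = draws, metadata = meta)
}
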