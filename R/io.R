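#' Write and read survey tables as delimited text
#'
#' Plain-CSV exchange format for effort segments, sightings and model-ready
#' cell tables.  Column schemas are those documented in [grid_effort()],
#' [assign_sightings()] and [build_cells()]; the same schemas apply to real
#' survey data prepared outside the package.
#'
#' @param x Data frame to write (effort segments, sightings, or cells).
#' @param path File path.
#' @return `read_survey_csv` returns a data frame with `date` columns
#'   restored to `Date`.
#' @export
write_survey_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  x <- utils::read.csv(path)
  if ("date" %in% names(x)) x$date <- as.Date(x$date)
  x
}

#' Write posterior summaries and run metadata of a fitted model
#'
#' Writes the parameter summary table (posterior mean, SD, quantiles, MC
#' error, R-hat) as CSV and, if `jsonlite` is installed, a JSON metadata
#' file with the MCMC configuration, seed, species/habitat form and
#' convergence flags.
#'
#' @param fit A fitted [cetadens()] model.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "cetadens"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sum_path <- file.path(dir, "posterior_summary.csv")
  utils::write.csv(summary(fit)$table, sum_path, row.names = TRUE)
  draws_path <- file.path(dir, "posterior_draws.csv")
  utils::write.csv(as.data.frame(posterior_draws(fit)), draws_path,
                   row.names = FALSE)
  paths <- c(sum_path, draws_path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(species_form = fit$species_form,
                 habitat_form = fit$habitat_form,
                 config = unclass(fit$config),
                 reference_mean = fit$reference_mean,
                 n_cells = nrow(fit$cells),
                 n_sightings = nrow(fit$sightings),
                 max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
                 converged = fit$converged,
                 dic = fit$dic["DIC"])
    meta_path <- file.path(dir, "run_metadata.json")
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    paths <- c(paths, meta_path)
  }
  invisible(paths)
}
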