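# The tidy concentration CSV dialect shared by the generator, the NCA layer
# and the pipeline: one row per observation, concentrations in ug/mL,
# doses in mg API per kg body weight.

.conc_columns <- c("subject_id", "species", "matrix", "analyte", "time_h",
                   "concentration_ug_per_ml", "dose_mg_per_kg")

#' Read a tidy concentration CSV
#'
#' @param path CSV path with columns `subject_id`, `species`, `matrix`
#'   (plasma/blood/liver/spleen), `analyte` (total/released/unconjugated),
#'   `time_h`, `concentration_ug_per_ml`, `dose_mg_per_kg`, optionally
#'   `censored`.
#' @return Validated data frame (a `censored` column is added as `FALSE`
#'   when absent).
#' @export
read_concentration_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.conc_columns, names(d))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  bad_mx <- setdiff(unique(d$matrix), c("plasma", "blood", "liver", "spleen"))
  if (length(bad_mx))
    stop("unknown matrix value(s): ", paste(bad_mx, collapse = ", "))
  bad_an <- setdiff(unique(d$analyte), c("total", "released", "unconjugated"))
  if (length(bad_an))
    stop("unknown analyte value(s): ", paste(bad_an, collapse = ", "))
  if (any(!is.finite(d$time_h)) || any(d$time_h < 0))
    stop("time_h must be finite and non-negative")
  if (any(!is.finite(d$concentration_ug_per_ml)))
    stop("concentration_ug_per_ml must be finite")
  if (!"censored" %in% names(d)) d$censored <- FALSE
  d
}

#' Write a tidy concentration CSV
#'
#' @param data Data frame carrying at least the tidy concentration columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_csv <- function(data, path) {
  miss <- setdiff(.conc_columns, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulated profiles as tidy CSV
#'
#' @param sim A `pbpk_sim` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(sim, path) {
  stopifnot(inherits(sim, "pbpk_sim"))
  utils::write.csv(sim$concentrations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
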