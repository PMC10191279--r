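# Study-level orchestration: per-species simulation across the clearance
# range, NCA of the simulated profiles, goodness of fit against observed
# (or synthetic) data, dose-normalised overlays and the human projection.

#' Fold error between an observation and a prediction
#'
#' `max(obs/pred, pred/obs)`: symmetric, always >= 1. Predictions within
#' 3-fold of measured concentrations are conventionally considered correct
#' in discovery-stage PBPK evaluation.
#'
#' @param observed,predicted Positive values (vectorised).
#' @return Fold error(s), >= 1.
#' @export
fold_error <- function(observed, predicted) {
  if (any(!is.finite(observed)) || any(!is.finite(predicted)) ||
      any(observed <= 0) || any(predicted <= 0))
    stop("observed and predicted must be strictly positive")
  pmax(observed / predicted, predicted / observed)
}

#' Goodness-of-fit summary against observed data
#'
#' Interpolates the simulated profile of each matrix x analyte at the
#' observation times and summarises prediction accuracy as the fraction of
#' observations within `fold` of their prediction, plus the maximum fold
#' error and the per-observation fold errors.
#'
#' @param observed Tidy concentration data frame (uncensored, positive
#'   concentrations are used).
#' @param sim A `pbpk_sim` covering the observation time span.
#' @param fold Accuracy bound (default 3).
#' @return List with `table` (per matrix x analyte: `n`,
#'   `fraction_within`, `max_fold_error`), `details` (per observation) and
#'   `overall_fraction`.
#' @export
gof_summary <- function(observed, sim, fold = 3) {
  stopifnot(inherits(sim, "pbpk_sim"))
  if ("censored" %in% names(observed)) observed <- observed[!observed$censored, ]
  observed <- observed[observed$concentration_ug_per_ml > 0, ]
  keys <- unique(observed[, c("matrix", "analyte")])
  details <- lapply(seq_len(nrow(keys)), function(i) {
    mx <- keys$matrix[i]
    an <- keys$analyte[i]
    o <- observed[observed$matrix == mx & observed$analyte == an, ]
    prof <- sim_profile(sim, mx, an)
    pred <- stats::approx(prof$time_h, prof$concentration_ug_per_ml,
                          xout = o$time_h, rule = 2)$y
    data.frame(matrix = mx, analyte = an, time_h = o$time_h,
               observed = o$concentration_ug_per_ml, predicted = pred,
               fold_error = fold_error(o$concentration_ug_per_ml, pred))
  })
  details <- do.call(rbind, details)
  agg <- lapply(split(details, interaction(details$matrix, details$analyte,
                                           drop = TRUE)), function(d)
    data.frame(matrix = d$matrix[1L], analyte = d$analyte[1L], n = nrow(d),
               fraction_within = mean(d$fold_error <= fold),
               max_fold_error = max(d$fold_error)))
  tab <- do.call(rbind, agg)
  rownames(tab) <- NULL
  list(table = tab, details = details,
       overall_fraction = mean(details$fold_error <= fold))
}

#' Dose-normalised overlay of concentration profiles
#'
#' Divides each profile's concentrations by its dose (per mg/kg) and stacks
#' the results in one long table, the form in which interspecies
#' superimposability is judged and human projections are compared against
#' preclinical data.
#'
#' @param ... Tidy concentration data frames, each carrying a
#'   `dose_mg_per_kg` column (simulated tables can be given a dose with
#'   [sim_tidy()]), optionally named to populate a `source` column.
#' @return Long data frame with `dn_concentration` =
#'   concentration / dose.
#' @export
dose_normalized_overlay <- function(...) {
  inputs <- list(...)
  if (!length(inputs)) stop("no profiles supplied")
  nms <- names(inputs)
  if (is.null(nms)) nms <- rep("", length(inputs))
  out <- lapply(seq_along(inputs), function(i) {
    d <- inputs[[i]]
    if (!"dose_mg_per_kg" %in% names(d) ||
        any(!is.finite(d$dose_mg_per_kg)) || any(d$dose_mg_per_kg <= 0))
      stop("every profile must carry a positive dose_mg_per_kg column")
    d$dn_concentration <- d$concentration_ug_per_ml / d$dose_mg_per_kg
    d$source <- if (nzchar(nms[i])) nms[i] else paste0("profile_", i)
    d
  })
  common <- Reduce(intersect, lapply(out, names))
  do.call(rbind, lapply(out, function(d) d[common]))
}

#' Simulated profiles as a tidy dosed table
#'
#' @param sim A `pbpk_sim`.
#' @return The tidy concentration table with `species` and
#'   `dose_mg_per_kg` columns attached.
#' @export
sim_tidy <- function(sim) {
  stopifnot(inherits(sim, "pbpk_sim"))
  d <- sim$concentrations
  d$species <- sim$model$physiology$species_name
  d$dose_mg_per_kg <- sim$regimen$dose
  d
}

#' Run the species-level analysis
#'
#' Simulates one species at its configured dose and regimen for each
#' clearance value in `cl_values` (default: the configured clearance
#' range, e.g. the nominal, in-vitro-scaled and in-vivo-measured values),
#' runs NCA on every simulated plasma profile, and, when observed data are
#' supplied, computes a goodness-of-fit summary against the first
#' clearance value's simulation. When `out_dir` is given, profile CSVs
#' (one per clearance value), the NCA table and a reproducibility manifest
#' listing every parameter used are written there.
#'
#' @param species Species name or config path.
#' @param cl_values Released-API clearance values to simulate, L/kg/h.
#' @param dose Dose, mg/kg (default: first configured study dose).
#' @param observed Optional tidy concentration data frame (or CSV path).
#' @param times Simulation grid.
#' @param out_dir Optional output directory.
#' @return List with `species`, `regimen`, `sims` (named by clearance),
#'   `nca` (simulated-profile NCA per clearance and analyte), `gof`
#'   (`NULL` without observations) and `manifest`.
#' @export
run_species <- function(species, cl_values = NULL, dose = NULL,
                        observed = NULL, times = default_time_grid(),
                        out_dir = NULL) {
  cfg <- load_species_config(species)
  if (is.null(cl_values))
    cl_values <- if (!is.null(cfg$released$CL_range)) cfg$released$CL_range
                 else cfg$released$CL
  if (is.null(dose)) dose <- cfg$study$dose_mg_per_kg[[1L]]
  regimen <- dose_regimen(dose, cfg$study$route,
                          cfg$study$infusion_duration_h)
  sims <- lapply(cl_values, function(cl)
    simulate_pbpk(load_species_model(species, CL = cl), regimen, times))
  names(sims) <- as.character(cl_values)

  nca_rows <- lapply(cl_values, function(cl) {
    sim <- sims[[as.character(cl)]]
    do.call(rbind, lapply(c("released", "total"), function(an) {
      prof <- sim_profile(sim, "plasma", an)
      cbind(data.frame(species = cfg$species, CL = cl, analyte = an),
            nca(prof$time_h, prof$concentration_ug_per_ml, dose,
                route = regimen$route))
    }))
  })
  nca_tab <- do.call(rbind, nca_rows)

  gof <- NULL
  if (!is.null(observed)) {
    if (is.character(observed)) observed <- read_concentration_csv(observed)
    gof <- gof_summary(observed, sims[[1L]])
  }

  manifest <- list(species = cfg$species, dose_mg_per_kg = dose,
                   route = regimen$route,
                   infusion_duration_h = regimen$infusion_duration,
                   cl_values = cl_values,
                   physiology = cfg$physiology, released = cfg$released,
                   conjugated = cfg$conjugated,
                   time_grid = c(n = length(times), t_end = max(times)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cl in cl_values)
      write_simulation_csv(sims[[as.character(cl)]],
                           file.path(out_dir, sprintf("%s_CL%g_profiles.csv",
                                                      cfg$species, cl)))
    utils::write.csv(nca_tab, file.path(out_dir,
                                        sprintf("%s_nca.csv", cfg$species)),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir,
                                         sprintf("%s_manifest.yaml",
                                                 cfg$species)))
  }
  list(species = cfg$species, regimen = regimen, sims = sims, nca = nca_tab,
       gof = gof, manifest = manifest)
}

#' Project human exposure profiles
#'
#' Simulates the human parameter set (scaled from mouse, clearance from
#' hepatocyte IVIVE) at the projection dose, runs NCA on the simulated
#' plasma profiles, and returns dose-normalised series for comparison with
#' preclinical data.
#'
#' @param dose Dose, mg/kg (default 10, as a bolus like the mouse study).
#' @param CL Human released-API clearance override, L/kg/h (default: the
#'   configured IVIVE-derived value).
#' @param times Simulation grid.
#' @return List with `sim`, `nca` (released and total plasma), and
#'   `dose_normalized` (tidy table with `dn_concentration`).
#' @export
project_human <- function(dose = 10, CL = NULL,
                          times = default_time_grid()) {
  model <- load_species_model("human", CL = CL)
  if (is.null(model$released$CL) || !is.finite(model$released$CL))
    stop("human clearance unresolved: supply CL or configure ivive")
  regimen <- dose_regimen(dose, "bolus")
  sim <- simulate_pbpk(model, regimen, times)
  nca_tab <- do.call(rbind, lapply(c("released", "total"), function(an) {
    prof <- sim_profile(sim, "plasma", an)
    cbind(data.frame(analyte = an),
          nca(prof$time_h, prof$concentration_ug_per_ml, dose))
  }))
  list(sim = sim, nca = nca_tab,
       dose_normalized = dose_normalized_overlay(human = sim_tidy(sim)))
}
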