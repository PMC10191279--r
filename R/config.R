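#' Load a species model from a configuration file
#'
#' Species parameter sets ship with the package as YAML files mirroring the
#' published tables field-for-field (one file per species under
#' `extdata/species/`). `V_NR` is always recomputed as
#' `1 - (V_Nb + V_L + V_S)`.
#'
#' @param species One of `"mouse"`, `"rat"`, `"dog"`, `"human"`, or a path
#'   to a YAML file with the same structure.
#' @param CL Optional override for the released-API clearance, L/kg/h.
#' @param H Optional override for the hematocrit.
#' @return A [pbpk_model()] with the raw config attached as attribute
#'   `"config"`.
#' @export
load_species_model <- function(species, CL = NULL, H = NULL) {
  cfg <- load_species_config(species)
  if (!is.null(H)) cfg$physiology$H <- H
  phys <- do.call(species_physiology,
                  c(list(species_name = cfg$species), cfg$physiology))
  rel <- cfg$released
  rel$CL_range <- NULL
  if (!is.null(CL)) rel$CL <- CL
  released <- do.call(released_params, rel)
  v_nr <- 1 - (phys$V_Nb + phys$V_L + phys$V_S)
  conjugated <- do.call(conjugated_params, c(list(V_NR = v_nr), cfg$conjugated))
  model <- pbpk_model(phys, released, conjugated)
  attr(model, "config") <- cfg
  model
}

#' Load the raw species configuration list
#'
#' @inheritParams load_species_model
#' @return The parsed YAML as a nested list (blocks `species`, `physiology`,
#'   `released`, `conjugated`, `ivive`, `study`).
#' @export
load_species_config <- function(species) {
  path <- if (file.exists(species)) species else
    system.file("extdata", "species", paste0(species, ".yaml"),
                package = "dendripbpk")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("no packaged configuration for species '%s'", species))
  cfg <- yaml::read_yaml(path)
  need <- c("species", "physiology", "released", "conjugated")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(sprintf("configuration %s is missing block(s): %s", path,
                 paste(miss, collapse = ", ")))
  cfg
}

#' Write a species model back to the packaged configuration format
#'
#' @param model A [pbpk_model()].
#' @param path Output YAML path.
#' @param extra Optional named list merged into the top level (for example
#'   an `ivive` or `study` block).
#' @return `path`, invisibly.
#' @export
write_species_config <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "pbpk_model"))
  phys <- unclass(model$physiology)
  cfg <- c(list(species = phys$species_name,
                physiology = phys[setdiff(names(phys), "species_name")],
                released = unclass(model$released),
                conjugated = unclass(model$conjugated)),
           extra)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Published NCA reference table
#'
#' The printed per-study non-compartmental results for the nanoparticle
#' (total and released API plasma AUC, half-life and clearance per species
#' and dose group), shipped as package data and used as inputs to the
#' dose-proportionality and relative-exposure computations.
#'
#' @return A data frame with one row per species x dose group.
#' @export
nca_reference <- function() {
  utils::read.csv(system.file("extdata", "reference", "nca_reference.csv",
                              package = "dendripbpk"))
}

#' Published unconjugated-API reference table
#'
#' Printed clearance comparison for the API dosed in conventional
#' formulation: plasma AUC of the unconjugated API, hepatocyte Clint, and
#' predicted/measured blood and plasma clearances per species.
#'
#' @return A data frame with one row per species.
#' @export
unconjugated_reference <- function() {
  utils::read.csv(system.file("extdata", "reference",
                              "unconjugated_reference.csv",
                              package = "dendripbpk"))
}
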