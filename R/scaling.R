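# Interspecies scaling of the drug-specific parameter blocks. The mouse set
# is the fitted reference; rat, dog and human sets are derived from it by
# three rules: blood-unbound-fraction correction for apparent volumes and
# binding terms, body-weight allometry for the blood/rest flow, and
# organ-blood-flow ratios for the nanoparticle extravasation rates.

#' Fraction unbound in blood
#'
#' `fu_blood = fup / BPR`: plasma protein binding translated to whole blood
#' through the blood-to-plasma concentration ratio.
#'
#' @param fup Fraction unbound in plasma (> 0).
#' @param BPR Blood-to-plasma concentration ratio (> 0).
#' @return Fraction unbound in blood.
#' @examples
#' fu_blood(0.03, 0.84) # mouse, 0.0357
#' @export
fu_blood <- function(fup, BPR) {
  if (any(!is.finite(c(fup, BPR))) || any(c(fup, BPR) <= 0))
    stop("fup and BPR must be strictly positive")
  fup / BPR
}

#' Scaling context between two species
#'
#' Carries the source (mouse) and target physiologies plus the allometric
#' exponent, and precomputes the blood-unbound-fraction ratio used by the
#' volume and binding rules.
#'
#' @param source A [species_physiology()] for the reference species (mouse).
#' @param target A [species_physiology()] for the target species.
#' @param allometric_exponent Power-law exponent for flow scaling
#'   (default 0.7, the standard value for clearance-like quantities).
#' @return An object of class `scaling_context`.
#' @export
scaling_context <- function(source, target, allometric_exponent = 0.7) {
  stopifnot(inherits(source, "species_physiology"),
            inherits(target, "species_physiology"))
  structure(list(source = source, target = target,
                 allometric_exponent = allometric_exponent,
                 fu_ratio = fu_blood(target$fup, target$BPR) /
                   fu_blood(source$fup, source$BPR)),
            class = "scaling_context")
}

#' Scale an apparent volume between species
#'
#' Applies the blood-protein-binding correction
#' `V_target = V_source * fu_blood(target) / fu_blood(source)`; used for the
#' released-API central (`V_b`) and peripheral (`V_R`) volumes.
#'
#' @param V Source-species volume, L/kg.
#' @param ctx A [scaling_context()].
#' @return Target-species volume, L/kg.
#' @export
scale_volume <- function(V, ctx) {
  stopifnot(inherits(ctx, "scaling_context"))
  V * ctx$fu_ratio
}

#' Scale a flow allometrically
#'
#' Standard power-law scaling on absolute flows: the per-kg flow is
#' converted to L/h via the source body weight, scaled with
#' `(BW_target/BW_source)^b`, and re-normalised per kg of target body
#' weight. With exponent 1 the per-kg flow is unchanged.
#'
#' @param Q Source-species flow, L/kg/h.
#' @param ctx A [scaling_context()].
#' @return Target-species flow, L/kg/h.
#' @export
scale_flow_allometric <- function(Q, ctx) {
  stopifnot(inherits(ctx, "scaling_context"))
  bw_s <- ctx$source$BW
  bw_t <- ctx$target$BW
  (Q * bw_s) * (bw_t / bw_s)^ctx$allometric_exponent / bw_t
}

# Parameters the binding rule may touch; dissociation constants and the
# spleen conjugated partition coefficient are held constant across species.
.scalable_binding <- c("P_L", "P_S", "Bmax_L", "Bmax_S", "K_NBL")
.fixed_binding <- c("KD_L", "KD_S", "K_NBS")

#' Scale a binding/partition parameter between species
#'
#' Multiplicative blood-unbound-fraction scaling, applicable to the
#' non-specific partition terms (`P_L`, `P_S`), the maximum binding
#' capacities (`Bmax_L`, `Bmax_S`) and the conjugated liver/blood partition
#' coefficient (`K_NBL`). The dissociation constants `KD_L`/`KD_S` and the
#' spleen coefficient `K_NBS` are constant across species and attempting to
#' scale them is a contract violation.
#'
#' @param K Source-species parameter value.
#' @param ctx A [scaling_context()].
#' @param parameter Which parameter is being scaled (one of `"P_L"`,
#'   `"P_S"`, `"Bmax_L"`, `"Bmax_S"`, `"K_NBL"`).
#' @return Target-species parameter value.
#' @export
scale_binding <- function(K, ctx, parameter) {
  stopifnot(inherits(ctx, "scaling_context"))
  if (parameter %in% .fixed_binding)
    stop(sprintf("'%s' is held constant across species and must not be scaled",
                 parameter))
  parameter <- match.arg(parameter, .scalable_binding)
  K * ctx$fu_ratio
}

#' Scale a nanoparticle extravasation rate between species
#'
#' Extravasation is treated as a fixed fraction of the blood flow to the
#' organ, so rates scale with the organ-flow ratio between species:
#' blood-to-liver flow `Q_BL_i` for liver, blood/spleen flow `Q_BS` for
#' spleen.
#'
#' @param N Source-species extravasation rate, L/kg/h.
#' @param ctx A [scaling_context()].
#' @param organ `"liver"` or `"spleen"`.
#' @return Target-species rate, L/kg/h.
#' @export
scale_extravasation <- function(N, ctx, organ = c("liver", "spleen")) {
  stopifnot(inherits(ctx, "scaling_context"))
  organ <- match.arg(organ)
  q <- if (organ == "liver") "Q_BL_i" else "Q_BS"
  N * ctx$target[[q]] / ctx$source[[q]]
}

#' Build a species parameter bundle by scaling from mouse
#'
#' Derives the full released + conjugated parameter set for a target
#' species from the fitted mouse set: physiological entries are fixed to
#' their literature values from the target configuration; `V_b`, `V_R` use
#' the blood-binding volume rule; `Q_BR` allometry; `P_L`, `P_S`, `Bmax_L`,
#' `Bmax_S`, `K_NBL` the binding rule; `N_BL`, `N_BS` the organ-flow rule;
#' release rate constants, vascular fractions, `KD_L`, `KD_S`, `K_NBS` and
#' `N_BR = 0` are copied unchanged; `V_NR` is recomputed as
#' `1 - (V_Nb + V_L + V_S)`. `CL` is not produced by these rules (it comes
#' from IVIVE or in-vivo measurement) and is taken from the target
#' configuration.
#'
#' The scaled values are cross-checked against the published target values
#' shipped in the species configuration; any entry that differs by more
#' than `tolerance` *and* does not round to the published value at its
#' printed precision triggers a warning (see [compare_scaled_params()]).
#'
#' @param species Target species: `"rat"`, `"dog"` or `"human"` (`"mouse"`
#'   returns the mouse bundle unchanged).
#' @param allometric_exponent Passed to [scaling_context()].
#' @param tolerance Relative tolerance for the cross-check (default 0.05).
#' @param quiet Suppress the cross-check warning.
#' @return A [pbpk_model()] whose drug-specific entries are the *scaled*
#'   values, with the comparison table attached as attribute `"comparison"`.
#' @export
build_species_params <- function(species, allometric_exponent = 0.7,
                                 tolerance = 0.05, quiet = FALSE) {
  mouse <- load_species_model("mouse")
  if (identical(species, "mouse")) return(mouse)
  target_cfg <- load_species_config(species)
  target <- load_species_model(species)
  ctx <- scaling_context(mouse$physiology, target$physiology,
                         allometric_exponent)

  rel_m <- mouse$released
  rel <- released_params(
    V_b = scale_volume(rel_m$V_b, ctx),
    V_R = scale_volume(rel_m$V_R, ctx),
    Q_BR = scale_flow_allometric(rel_m$Q_BR, ctx),
    CL = target$released$CL,
    Bmax_L = scale_binding(rel_m$Bmax_L, ctx, "Bmax_L"),
    KD_L = rel_m$KD_L,
    P_L = scale_binding(rel_m$P_L, ctx, "P_L"),
    Bmax_S = scale_binding(rel_m$Bmax_S, ctx, "Bmax_S"),
    KD_S = rel_m$KD_S,
    P_S = scale_binding(rel_m$P_S, ctx, "P_S"))

  conj_m <- mouse$conjugated
  phys_t <- target$physiology
  conj <- conjugated_params(
    V_NR = 1 - (phys_t$V_Nb + phys_t$V_L + phys_t$V_S),
    N_BL = scale_extravasation(conj_m$N_BL, ctx, "liver"),
    N_BS = scale_extravasation(conj_m$N_BS, ctx, "spleen"),
    N_BR = 0,
    K_NBL = scale_binding(conj_m$K_NBL, ctx, "K_NBL"),
    K_NBS = conj_m$K_NBS,
    krel_b = conj_m$krel_b, krel_L = conj_m$krel_L,
    krel_S = conj_m$krel_S, krel_R = conj_m$krel_R)

  model <- pbpk_model(phys_t, rel, conj)
  cmp <- compare_scaled_params(model, target, tolerance = tolerance)
  attr(model, "comparison") <- cmp
  if (!quiet && any(!cmp$within))
    warning(sprintf(
      "scaled %s parameter(s) differ from the published values beyond %g%% + printed rounding: %s",
      species, 100 * tolerance,
      paste(cmp$parameter[!cmp$within], collapse = ", ")))
  model
}

# Entries produced by the scaling rules (published counterparts exist).
.scaled_entries <- list(
  released = c("V_b", "V_R", "Q_BR", "Bmax_L", "P_L", "Bmax_S", "P_S"),
  conjugated = c("N_BL", "N_BS", "K_NBL"))

#' Compare a scaled bundle against published values
#'
#' For every parameter produced by the scaling rules, tabulates the scaled
#' value, the published (printed) value, their relative difference, and
#' whether the pair agrees within `tolerance` *or* within the rounding
#' implied by the printed precision (a scaled value that rounds to the
#' printed number at its number of significant digits is considered in
#' agreement: several published entries are printed to 1-2 significant
#' figures).
#'
#' @param scaled A [pbpk_model()] carrying scaled values.
#' @param reference A [pbpk_model()] carrying the published values.
#' @param tolerance Relative tolerance (default 0.05).
#' @return Data frame with columns `parameter`, `scaled`, `published`,
#'   `rel_diff`, `within`.
#' @export
compare_scaled_params <- function(scaled, reference, tolerance = 0.05) {
  rows <- lapply(names(.scaled_entries), function(block) {
    nms <- .scaled_entries[[block]]
    data.frame(parameter = nms,
               scaled = unlist(scaled[[block]][nms], use.names = FALSE),
               published = unlist(reference[[block]][nms], use.names = FALSE))
  })
  d <- do.call(rbind, rows)
  d$rel_diff <- abs(d$scaled - d$published) / d$published
  d$within <- d$rel_diff <= tolerance |
    mapply(rounds_to_printed, d$scaled, d$published)
  d
}

# TRUE when `value` rounds to `printed` at the precision `printed` carries
# (its count of significant digits); covers table entries printed to 1-2
# significant figures where 5% is tighter than the printed resolution.
rounds_to_printed <- function(value, printed) {
  if (printed == 0) return(value == 0)
  digits <- vapply(seq_len(8), function(k)
    isTRUE(all.equal(signif(printed, k), printed, tolerance = 1e-12)),
    logical(1))
  k <- which(digits)[1L]
  if (is.na(k)) k <- 8L
  identical(signif(value, k), signif(printed, k))
}
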