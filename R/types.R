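#' Species physiology
#'
#' Fixed anatomical and physiological constants for one species. Volumes and
#' flows are expressed per kg body weight so that the same equations apply
#' across species; amounts elsewhere in the package are correspondingly
#' carried as mg per kg body weight.
#'
#' @param species_name Species label (e.g. `"mouse"`).
#' @param BW Body weight, kg.
#' @param V_L,V_S Liver and spleen volumes, L/kg.
#' @param V_Nb Blood volume (conjugated-API central volume), L/kg.
#' @param Q_BL_i Blood-to-liver flow, L/kg/h. Must equal `Q_BL_o - Q_BS`
#'   within 1%: hepatic arterial + portal inflow, with the splenic flow
#'   entering the liver via the portal route.
#' @param Q_BL_o Liver-to-blood flow, L/kg/h.
#' @param Q_BS Blood/spleen flow, L/kg/h.
#' @param H Hematocrit, fraction of blood volume occupied by red cells.
#' @param fup Fraction of API unbound in plasma.
#' @param BPR Blood-to-plasma concentration ratio of the API.
#' @param v_liver,v_spleen Vascular volume fractions of liver and spleen.
#' @return An object of class `species_physiology`.
#' @export
species_physiology <- function(species_name, BW, V_L, V_S, V_Nb,
                               Q_BL_i, Q_BL_o, Q_BS, H, fup, BPR,
                               v_liver, v_spleen) {
  num <- c(BW = BW, V_L = V_L, V_S = V_S, V_Nb = V_Nb, Q_BL_i = Q_BL_i,
           Q_BL_o = Q_BL_o, Q_BS = Q_BS, H = H, fup = fup, BPR = BPR,
           v_liver = v_liver, v_spleen = v_spleen)
  if (any(!is.finite(num)))
    stop("all physiological constants must be finite numbers")
  pos <- c("BW", "V_L", "V_S", "V_Nb", "Q_BL_i", "Q_BL_o", "Q_BS", "BPR")
  if (any(num[pos] <= 0))
    stop("volumes, flows, BW and BPR must be strictly positive")
  if (H <= 0 || H >= 1) stop("hematocrit must lie strictly between 0 and 1")
  if (fup <= 0 || fup > 1) stop("fup must lie in (0, 1]")
  if (v_liver < 0 || v_liver > 1 || v_spleen < 0 || v_spleen > 1)
    stop("vascular volume fractions must lie in [0, 1]")
  if (abs(Q_BL_i - (Q_BL_o - Q_BS)) > 0.01 * Q_BL_i)
    stop("Q_BL_i must equal Q_BL_o - Q_BS within 1% (portal flow balance)")
  structure(c(list(species_name = species_name), as.list(num)),
            class = "species_physiology")
}

#' Released-API parameter block
#'
#' Drug-specific parameters of the released (free) API: apparent central and
#' peripheral volumes, intercompartmental clearance, liver intrinsic
#' clearance, and the saturable liver/spleen partition parameters.
#' `Bmax` and `KD` are in ng/mL, the unit in which they were fitted;
#' [partition_coefficient()] converts blood concentrations accordingly.
#'
#' @param V_b Apparent central (blood) volume, L/kg.
#' @param V_R Apparent peripheral ("rest") volume, L/kg.
#' @param Q_BR Blood/rest intercompartmental clearance, L/kg/h.
#' @param CL Released-API liver clearance, L/kg/h.
#' @param Bmax_L,KD_L Liver saturable binding capacity and dissociation
#'   constant, ng/mL.
#' @param P_L Liver non-specific partition term, dimensionless.
#' @param Bmax_S,KD_S,P_S Spleen analogues.
#' @return An object of class `released_params`.
#' @export
released_params <- function(V_b, V_R, Q_BR, CL, Bmax_L, KD_L, P_L,
                            Bmax_S, KD_S, P_S) {
  num <- c(V_b = V_b, V_R = V_R, Q_BR = Q_BR, CL = CL, Bmax_L = Bmax_L,
           KD_L = KD_L, P_L = P_L, Bmax_S = Bmax_S, KD_S = KD_S, P_S = P_S)
  if (any(!is.finite(num)) || any(num < 0))
    stop("released-API parameters must be finite and non-negative")
  if (KD_L <= 0 || KD_S <= 0) stop("dissociation constants must be positive")
  if (V_b <= 0 || V_R <= 0) stop("apparent volumes must be positive")
  structure(as.list(num), class = "released_params")
}

#' Conjugated-API parameter block
#'
#' Drug-specific parameters of the nanoparticle-conjugated API:
#' extravasation rates into tissues, tissue/blood partition coefficients and
#' the compartment-specific first-order API release rate constants.
#'
#' @param V_NR Conjugated-API rest volume, L/kg; by construction
#'   `1 - (V_Nb + V_L + V_S)` and must be positive.
#' @param N_BL,N_BS,N_BR Blood/liver, blood/spleen and blood/rest
#'   extravasation (distribution) rates, L/kg/h.
#' @param K_NBL,K_NBS Conjugated-API liver/blood and spleen/blood partition
#'   coefficients, dimensionless.
#' @param krel_b,krel_L,krel_S,krel_R First-order API release rate constants
#'   in blood, liver, spleen and rest, 1/h.
#' @return An object of class `conjugated_params`.
#' @export
conjugated_params <- function(V_NR, N_BL, N_BS, N_BR, K_NBL, K_NBS,
                              krel_b, krel_L, krel_S, krel_R) {
  num <- c(V_NR = V_NR, N_BL = N_BL, N_BS = N_BS, N_BR = N_BR,
           K_NBL = K_NBL, K_NBS = K_NBS, krel_b = krel_b, krel_L = krel_L,
           krel_S = krel_S, krel_R = krel_R)
  if (any(!is.finite(num)) || any(num < 0))
    stop("conjugated-API parameters must be finite and non-negative")
  if (K_NBL <= 0 || K_NBS <= 0)
    stop("conjugated partition coefficients must be positive")
  if (V_NR <= 0) stop("V_NR = 1 - sum(tissue volumes) must be positive")
  structure(as.list(num), class = "conjugated_params")
}

#' Dosing regimen
#'
#' @param dose Dose in mg API per kg body weight.
#' @param route `"bolus"` or `"infusion"`.
#' @param infusion_duration Duration of a constant-rate infusion, h
#'   (0 and ignored for a bolus).
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose, route = c("bolus", "infusion"),
                         infusion_duration = 0) {
  route <- match.arg(route)
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive")
  if (!is.finite(infusion_duration) || infusion_duration < 0)
    stop("infusion_duration must be non-negative")
  if (route == "infusion" && infusion_duration <= 0)
    stop("an infusion requires a positive infusion_duration")
  if (route == "bolus") infusion_duration <- 0
  structure(list(dose = dose, route = route,
                 infusion_duration = infusion_duration),
            class = "dose_regimen")
}

#' Assemble a PBPK model
#'
#' Bundles the physiology and the two drug-specific parameter blocks for one
#' species. If `conjugated$V_NR` disagrees with `1 - (V_Nb + V_L + V_S)` by
#' more than 1% an error is raised; use [conjugated_params()] with the
#' recomputed value.
#'
#' @param physiology A [species_physiology()] object.
#' @param released A [released_params()] object.
#' @param conjugated A [conjugated_params()] object.
#' @return An object of class `pbpk_model`.
#' @export
pbpk_model <- function(physiology, released, conjugated) {
  stopifnot(inherits(physiology, "species_physiology"),
            inherits(released, "released_params"),
            inherits(conjugated, "conjugated_params"))
  v_nr <- 1 - (physiology$V_Nb + physiology$V_L + physiology$V_S)
  if (abs(conjugated$V_NR - v_nr) > 0.01 * v_nr)
    stop(sprintf("V_NR (%.4f) is not 1 - sum(tissue volumes) (%.4f)",
                 conjugated$V_NR, v_nr))
  structure(list(physiology = physiology, released = released,
                 conjugated = conjugated),
            class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s (BW %.3g kg)\n", x$physiology$species_name,
              x$physiology$BW))
  cat(sprintf("  released : V_b %.3g, V_R %.3g L/kg; CL %.3g L/kg/h\n",
              x$released$V_b, x$released$V_R, x$released$CL))
  cat(sprintf("  conjugated: V_Nb %.3g, V_NR %.3g L/kg; krel_b %.3g 1/h\n",
              x$physiology$V_Nb, x$conjugated$V_NR, x$conjugated$krel_b))
  invisible(x)
}

# Replace one or more scalar parameters anywhere in a model bundle.
# Used by the sensitivity and fitting machinery; names must already exist.
set_model_param <- function(model, values) {
  stopifnot(inherits(model, "pbpk_model"))
  for (nm in names(values)) {
    hit <- FALSE
    for (block in c("released", "conjugated", "physiology")) {
      if (nm %in% names(model[[block]])) {
        model[[block]][[nm]] <- values[[nm]]
        hit <- TRUE
        break
      }
    }
    if (!hit) stop(sprintf("unknown model parameter '%s'", nm))
  }
  model
}

# Fetch a scalar parameter from whichever block holds it.
get_model_param <- function(model, name) {
  for (block in c("released", "conjugated", "physiology")) {
    if (name %in% names(model[[block]])) return(model[[block]][[name]])
  }
  stop(sprintf("unknown model parameter '%s'", name))
}
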