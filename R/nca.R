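# Non-compartmental analysis: model-free PK metrics from concentration-time
# profiles. These are the quantities the in-vivo studies report (AUC,
# terminal half-life, clearance, dose-normalised exposure) plus the
# dose-proportionality and relative-exposure summaries built on them.

#' Trapezoidal area under the curve
#'
#' AUC to the last point. `"linear"` applies the trapezoidal rule
#' throughout; `"linear-up-log-down"` (the usual PK convention and the
#' default elsewhere in the package) uses the log-trapezoid on declining
#' segments with two positive endpoints, which is exact for mono-exponential
#' decay.
#'
#' @param times Strictly increasing sampling times, h.
#' @param concentrations Non-negative concentrations, ug/mL.
#' @param method `"linear-up-log-down"` or `"linear"`.
#' @return AUC, ug/mL * h.
#' @export
auc_trapezoid <- function(times, concentrations,
                          method = c("linear-up-log-down", "linear")) {
  method <- match.arg(method)
  n <- length(times)
  if (n < 2L) stop("at least two time points are required")
  if (length(concentrations) != n)
    stop("times and concentrations must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and non-negative")
  dt <- diff(times)
  c1 <- concentrations[-n]
  c2 <- concentrations[-1L]
  lin <- dt * (c1 + c2) / 2
  if (method == "linear") return(sum(lin))
  logdown <- c2 < c1 & c2 > 0
  seg <- lin
  seg[logdown] <- dt[logdown] * (c1[logdown] - c2[logdown]) /
    log(c1[logdown] / c2[logdown])
  sum(seg)
}

#' Terminal half-life by log-linear regression
#'
#' Fits `log(C)` against time over candidate terminal windows (the last
#' `k >= 3` positive points after the observed maximum, for every feasible
#' `k`) and keeps the window maximising the adjusted R-squared, the usual
#' automatic lambda-z selection. The estimate is flagged unreliable when
#' the best fit has R-squared below `min_r_squared` or a non-negative
#' slope.
#'
#' @param times Strictly increasing sampling times, h.
#' @param concentrations Concentrations, ug/mL.
#' @param min_r_squared Minimum acceptable R-squared (default 0.8).
#' @return List with `half_life` (h; `NA` when not estimable), `lambda_z`
#'   (1/h), `n_points`, `r_squared`, `adj_r_squared`, `reliable`.
#' @export
terminal_half_life <- function(times, concentrations, min_r_squared = 0.8) {
  keep <- is.finite(concentrations) & concentrations > 0
  tt <- times[keep]
  cc <- concentrations[keep]
  not_estimable <- list(half_life = NA_real_, lambda_z = NA_real_,
                        n_points = 0L, r_squared = NA_real_,
                        adj_r_squared = NA_real_, reliable = FALSE)
  if (length(tt) < 3L) return(not_estimable)
  i_max <- which.max(cc)
  tail_idx <- seq(i_max, length(tt))
  if (length(tail_idx) < 3L) tail_idx <- seq(length(tt) - 2L, length(tt))
  best <- NULL
  for (k in 3:length(tail_idx)) {
    idx <- utils::tail(tail_idx, k)
    x <- tt[idx]
    y <- log(cc[idx])
    if (stats::sd(y) == 0) next   # flat profile: zero slope, no half-life
    fit <- stats::lm.fit(cbind(1, x), y)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    r2 <- 1 - ssr / sst
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj) {
      best <- list(slope = unname(fit$coefficients[2L]), r2 = r2, adj = adj,
                   k = k)
    }
  }
  if (is.null(best)) return(not_estimable)
  reliable <- best$slope < 0 && best$r2 >= min_r_squared
  lambda <- abs(best$slope)
  list(half_life = if (best$slope < 0) log(2) / lambda else NA_real_,
       lambda_z = if (best$slope < 0) lambda else NA_real_,
       n_points = best$k, r_squared = best$r2, adj_r_squared = best$adj,
       reliable = reliable)
}

#' Clearance from dose and exposure
#'
#' `CL = dose / AUC`, with dose in mg/kg and AUC in ug/mL * h
#' (= mg h / L), giving L/h/kg.
#'
#' @param dose Dose, mg/kg.
#' @param AUC Area under the curve, ug/mL * h.
#' @return Clearance, L/h/kg.
#' @export
clearance_from_auc <- function(dose, AUC) {
  if (any(!is.finite(AUC)) || any(AUC <= 0))
    stop("AUC must be strictly positive")
  dose / AUC
}

#' Dose-proportionality slope through the origin
#'
#' Least-squares slope of AUC against dose constrained through the origin:
#' `slope = sum(dose * AUC) / sum(dose^2)`. Exposure proportional to dose
#' appears as a common slope across dose groups and species.
#'
#' @param doses Doses, mg/kg.
#' @param AUCs Matching AUCs, ug/mL * h.
#' @return Slope, ug/mL * h per mg/kg.
#' @export
dose_proportionality_slope <- function(doses, AUCs) {
  if (length(doses) != length(AUCs) || length(doses) < 1L)
    stop("doses and AUCs must be matched, non-empty vectors")
  if (all(doses == 0)) stop("at least one dose must be non-zero")
  sum(doses * AUCs) / sum(doses^2)
}

#' Relative exposure of released vs unconjugated API
#'
#' Percent ratio of dose-normalised exposures: how much higher the
#' nanoparticle-released API exposure is than the same API dosed in
#' conventional (unconjugated) formulation.
#'
#' @param released_dnAUC Dose-normalised AUC of nanoparticle-released API.
#' @param unconjugated_dnAUC Dose-normalised AUC of unconjugated API.
#' @return Percent (100 = equal exposure).
#' @export
relative_exposure <- function(released_dnAUC, unconjugated_dnAUC) {
  if (any(!is.finite(c(released_dnAUC, unconjugated_dnAUC))) ||
      any(c(released_dnAUC, unconjugated_dnAUC) <= 0))
    stop("dose-normalised AUCs must be strictly positive")
  100 * released_dnAUC / unconjugated_dnAUC
}

#' Back-extrapolated initial concentration (bolus)
#'
#' Log-linear extrapolation to t = 0 from the first two positive
#' concentrations; reported for information only and not used in AUC.
#'
#' @param times Strictly increasing sampling times, h.
#' @param concentrations Concentrations, ug/mL.
#' @return C0, ug/mL (`NA` when fewer than two positive points or the
#'   profile rises initially).
#' @export
back_extrapolate_c0 <- function(times, concentrations) {
  keep <- which(is.finite(concentrations) & concentrations > 0)
  if (length(keep) < 2L) return(NA_real_)
  i <- keep[1:2]
  if (concentrations[i[2L]] >= concentrations[i[1L]]) return(NA_real_)
  slope <- (log(concentrations[i[2L]]) - log(concentrations[i[1L]])) /
    (times[i[2L]] - times[i[1L]])
  exp(log(concentrations[i[1L]]) - slope * times[i[1L]])
}

#' Non-compartmental analysis of one profile
#'
#' @param times Strictly increasing sampling times, h.
#' @param concentrations Concentrations, ug/mL.
#' @param dose Dose, mg/kg.
#' @param route `"bolus"` or `"infusion"` (controls C0 back-extrapolation).
#' @param method AUC method, see [auc_trapezoid()].
#' @return One-row data frame: `AUC_last`, `AUC_inf` (`NA` when the
#'   terminal phase is not estimable), `half_life`, `CL` (dose/AUC_last),
#'   `C0`, `dose`, `dose_normalized_AUC`, `half_life_reliable`.
#' @export
nca <- function(times, concentrations, dose, route = c("bolus", "infusion"),
                method = c("linear-up-log-down", "linear")) {
  route <- match.arg(route)
  method <- match.arg(method)
  auc <- auc_trapezoid(times, concentrations, method)
  hl <- terminal_half_life(times, concentrations)
  clast <- utils::tail(concentrations[concentrations > 0], 1L)
  auc_inf <- if (!is.na(hl$lambda_z) && length(clast) == 1L)
    auc + clast / hl$lambda_z else NA_real_
  data.frame(
    AUC_last = auc,
    AUC_inf = auc_inf,
    half_life = hl$half_life,
    CL = clearance_from_auc(dose, auc),
    C0 = if (route == "bolus") back_extrapolate_c0(times, concentrations)
         else NA_real_,
    dose = dose,
    dose_normalized_AUC = auc / dose,
    half_life_reliable = hl$reliable)
}

#' NCA over a tidy concentration table
#'
#' Runs [nca()] per species x dose x matrix x analyte profile of a tidy
#' concentration table (the dialect written by [generate_dataset()] and
#' [write_concentration_csv()]). Replicate animals at a time point are
#' aggregated to their mean concentration first (destructive sampling gives
#' a composite profile, as in the reported study tables); censored
#' observations are dropped.
#'
#' @param data Tidy concentration data frame with columns `species`,
#'   `matrix`, `analyte`, `time_h`, `concentration_ug_per_ml`,
#'   `dose_mg_per_kg` (and optionally `censored`).
#' @param route Passed to [nca()].
#' @param method AUC method.
#' @return Data frame with one NCA row per profile.
#' @export
nca_table <- function(data, route = c("bolus", "infusion"),
                      method = c("linear-up-log-down", "linear")) {
  route <- match.arg(route)
  method <- match.arg(method)
  need <- c("species", "matrix", "analyte", "time_h",
            "concentration_ug_per_ml", "dose_mg_per_kg")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if ("censored" %in% names(data)) data <- data[!data$censored, ]
  key <- interaction(data$species, data$dose_mg_per_kg, data$matrix,
                     data$analyte, drop = TRUE)
  rows <- lapply(split(data, key), function(d) {
    prof <- stats::aggregate(concentration_ug_per_ml ~ time_h, d, mean)
    prof <- prof[order(prof$time_h), ]
    res <- if (nrow(prof) >= 2L) {
      nca(prof$time_h, prof$concentration_ug_per_ml,
          dose = d$dose_mg_per_kg[1L], route = route, method = method)
    } else {
      # single-time-point profiles (sparse necropsy sampling) carry no AUC
      data.frame(AUC_last = NA_real_, AUC_inf = NA_real_,
                 half_life = NA_real_, CL = NA_real_, C0 = NA_real_,
                 dose = d$dose_mg_per_kg[1L],
                 dose_normalized_AUC = NA_real_,
                 half_life_reliable = FALSE)
    }
    cbind(data.frame(species = d$species[1L], matrix = d$matrix[1L],
                     analyte = d$analyte[1L]), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
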