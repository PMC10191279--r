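# Independent numerical oracles used across the test files. The derivative
# function and the fixed-step integrator below are written directly from
# the model equations, independently of the package's solver path, so that
# trajectory tests compare two separate routes to the same system.

# Mouse parameter values transcribed once for oracle use.
oracle_mouse <- list(
  V_b = 0.34, V_L = 0.065, V_S = 0.005, V_R = 0.1, V_Nb = 0.085,
  V_NR = 1 - (0.085 + 0.065 + 0.005),
  Q_BL_i = 8.36, Q_BL_o = 9.1, Q_BS = 0.74, Q_BR = 0.015, CL = 1,
  Bmax_L = 49.6, KD_L = 0.6, P_L = 0.76,
  Bmax_S = 125.9, KD_S = 0.63, P_S = 0.17,
  N_BL = 3e-4, N_BS = 2e-5, N_BR = 0, K_NBL = 0.9, K_NBS = 1000,
  krel_b = 0.125, krel_L = 0.016, krel_S = 0.0063, krel_R = 0.125,
  BPR = 0.84, H = 0.45, v_liver = 0.125, v_spleen = 0.016)

# Hand-written derivative of the 8-state system (A_b, A_L, A_S, A_R,
# X_b, X_L, X_S, X_R), amounts mg/kg, concentrations mg/L; Bmax/KD in
# ng/mL hence the factor 1000 on the blood concentration.
oracle_derivs <- function(y, p) {
  Cb <- y[1] / p$V_b
  KBL <- p$Bmax_L / (1000 * Cb + p$KD_L) + p$P_L
  KBS <- p$Bmax_S / (1000 * Cb + p$KD_S) + p$P_S
  CXb <- y[5] / p$V_Nb
  fl <- p$N_BL * (CXb - y[6] / (p$V_L * p$K_NBL))
  fs <- p$N_BS * (CXb - y[7] / (p$V_S * p$K_NBS))
  fr <- p$N_BR * (CXb - y[8] / p$V_NR)
  c(-p$Q_BL_i * Cb + p$Q_BL_o * y[2] / (p$V_L * KBL) - p$Q_BS * Cb -
      p$Q_BR * (Cb - y[4] / p$V_R) + p$krel_b * y[5],
    p$Q_BL_i * Cb - p$Q_BL_o * y[2] / (p$V_L * KBL) -
      p$CL * y[2] / (p$V_L * KBL) + p$Q_BS * y[3] / (p$V_S * KBS) +
      p$krel_L * y[6],
    p$Q_BS * (Cb - y[3] / (p$V_S * KBS)) + p$krel_S * y[7],
    p$Q_BR * (Cb - y[4] / p$V_R) + p$krel_R * y[8],
    -fl - fs - fr - p$krel_b * y[5],
    fl - p$krel_L * y[6],
    fs - p$krel_S * y[7],
    fr - p$krel_R * y[8])
}

# Classical fixed-step 4th-order Runge-Kutta; returns the state at each
# requested output time (which must be multiples of the step).
oracle_rk4 <- function(y0, t_out, h, p) {
  t_end <- max(t_out)
  n <- round(t_end / h)
  out <- matrix(NA_real_, nrow = length(t_out), ncol = length(y0))
  y <- y0
  t <- 0
  idx <- round(t_out / h)
  hit <- match(0L, idx)
  if (!is.na(hit)) out[hit, ] <- y
  for (i in seq_len(n)) {
    k1 <- oracle_derivs(y, p)
    k2 <- oracle_derivs(y + h / 2 * k1, p)
    k3 <- oracle_derivs(y + h / 2 * k2, p)
    k4 <- oracle_derivs(y + h * k3, p)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    hit <- match(i, idx)
    if (!is.na(hit)) out[hit, ] <- y
  }
  out
}

# Trapezoidal AUC used as a cross-check on simple profiles.
oracle_trapz <- function(t, c) sum(diff(t) * (utils::head(c, -1) +
                                                utils::tail(c, -1)) / 2)
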