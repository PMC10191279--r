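test_that("saturable partition coefficient matches its closed form and limits", {
  # hand-evaluated at C = 0 with the mouse liver and spleen triples
  expect_equal(partition_coefficient(0, Bmax = 49.6, KD = 0.6, P = 0.76),
               49.6 / 0.6 + 0.76, tolerance = 1e-12)
  expect_equal(partition_coefficient(0, 49.6, 0.6, 0.76), 83.43,
               tolerance = 1e-4)
  expect_equal(partition_coefficient(0, 125.9, 0.63, 0.17), 200.0,
               tolerance = 1e-3)
  # saturation limit is the non-specific term
  expect_equal(partition_coefficient(1e9, 49.6, 0.6, 0.76), 0.76,
               tolerance = 1e-6)
  # strictly decreasing in concentration
  cc <- c(0, 1e-4, 1e-3, 0.01, 0.1, 1, 10)
  k <- partition_coefficient(cc, 49.6, 0.6, 0.76)
  expect_true(all(diff(k) < 0))
  expect_error(partition_coefficient(-1, 49.6, 0.6, 0.76), "non-negative")
  expect_error(partition_coefficient(1, 49.6, 0, 0.76), "positive")
})

test_that("released-API derivatives implement the flow/elimination/release balance", {
  m <- mouse_model
  zero <- c(A_b = 0, A_L = 0, A_S = 0, A_R = 0)
  expect_equal(unname(released_rhs(zero, m$released, m$physiology)),
               rep(0, 4))
  # single term: everything in blood drains at (Q_BL_i + Q_BS + Q_BR)/V_b
  d <- released_rhs(c(A_b = 1, A_L = 0, A_S = 0, A_R = 0),
                    m$released, m$physiology)
  expect_equal(unname(d[1L]), -(8.36 + 0.74 + 0.015) / 0.34,
               tolerance = 1e-12)
  expect_equal(unname(d[1L]), -26.81, tolerance = 1e-3)
  # with CL = 0 and no release the flow terms cancel pairwise
  m0 <- set_model_param(mouse_model, list(CL = 0))
  rel0 <- do.call(released_params, unclass(m0$released))
  for (state in list(c(A_b = 1, A_L = 0.3, A_S = 0.2, A_R = 0.05),
                     c(A_b = 0.01, A_L = 2, A_S = 0.5, A_R = 1))) {
    d <- released_rhs(state, rel0, m0$physiology)
    expect_equal(sum(d), 0, tolerance = 1e-12)
  }
  # derivative sum = release input - liver elimination
  st <- c(A_b = 0.5, A_L = 0.4, A_S = 0.1, A_R = 0.2)
  xs <- c(X_b = 2, X_L = 1, X_S = 0.5, X_R = 0.3)
  d <- released_rhs(st, m$released, m$physiology, xs, m$conjugated)
  kbl <- partition_coefficient(st[["A_b"]] / m$released$V_b,
                               m$released$Bmax_L, m$released$KD_L,
                               m$released$P_L)
  release_in <- with(m$conjugated, krel_b * 2 + krel_L * 1 + krel_S * 0.5 +
                       krel_R * 0.3)
  elim <- m$released$CL * st[["A_L"]] / (m$physiology$V_L * kbl)
  expect_equal(sum(d), release_in - elim, tolerance = 1e-10)
})

test_that("conjugated-API derivatives are release-driven with no carrier clearance", {
  m <- mouse_model
  expect_equal(unname(conjugated_rhs(c(X_b = 0, X_L = 0, X_S = 0, X_R = 0),
                                     m$conjugated, m$physiology)),
               rep(0, 4))
  d <- conjugated_rhs(c(X_b = 1, X_L = 0, X_S = 0, X_R = 0),
                      m$conjugated, m$physiology)
  expect_equal(unname(d[1L]), -(3e-4 + 2e-5) / 0.085 - 0.125,
               tolerance = 1e-12)
  expect_equal(unname(d[1L]), -0.12876, tolerance = 1e-4)
  # with N_BR = 0 the rest pool is driven only by its own release
  d <- conjugated_rhs(c(X_b = 5, X_L = 1, X_S = 1, X_R = 0),
                      m$conjugated, m$physiology)
  expect_identical(unname(d[4L]), 0)
  # derivative sum with no infusion equals minus the total release flux
  xs <- c(X_b = 2, X_L = 1.5, X_S = 0.7, X_R = 0.2)
  d <- conjugated_rhs(xs, m$conjugated, m$physiology)
  expect_equal(sum(d),
               -with(m$conjugated, krel_b * 2 + krel_L * 1.5 +
                       krel_S * 0.7 + krel_R * 0.2),
               tolerance = 1e-12)
  # zero-order infusion input adds to the blood derivative only
  d2 <- conjugated_rhs(xs, m$conjugated, m$physiology, infusion_rate = 3)
  expect_equal(unname(d2 - d), c(3, 0, 0, 0), tolerance = 1e-12)
  expect_error(conjugated_rhs(xs, m$conjugated, m$physiology, -1),
               "non-negative")
})

test_that("simulated trajectories conserve mass and respect totals >= released", {
  # with CL = 0 nothing leaves the system after a bolus
  m0 <- set_model_param(mouse_model, list(CL = 0))
  s0 <- simulate_pbpk(m0, mouse_bolus, coarse_grid())
  total_amount <- rowSums(s0$states)
  expect_lt(max(abs(total_amount - 10)) / 10, 1e-6)
  # with CL > 0 the cumulative liver elimination accounts for the loss
  s <- simulate_pbpk(mouse_model, mouse_bolus, coarse_grid())
  kbl <- partition_coefficient(s$states[, "A_b"] / mouse_model$released$V_b,
                               mouse_model$released$Bmax_L,
                               mouse_model$released$KD_L,
                               mouse_model$released$P_L)
  elim_rate <- mouse_model$released$CL * s$states[, "A_L"] /
    (mouse_model$physiology$V_L * kbl)
  eliminated <- cumsum(c(0, diff(s$times) *
                           (head(elim_rate, -1) + tail(elim_rate, -1)) / 2))
  expect_lt(max(abs(rowSums(s$states) + eliminated - 10)) / 10, 1e-3)
  # infusion: everything administered is present at end of infusion (CL = 0)
  d0 <- set_model_param(dog_model, list(CL = 0))
  si <- simulate_pbpk(d0, dog_infusion, coarse_grid(24))
  expect_equal(rowSums(si$states)[si$times == 0.5][[1]], 12,
               tolerance = 1e-6)
  # totals never fall below released anywhere
  tidy <- s$concentrations
  for (mx in unique(tidy$matrix)) {
    rel <- tidy$concentration_ug_per_ml[tidy$matrix == mx &
                                          tidy$analyte == "released"]
    tot <- tidy$concentration_ug_per_ml[tidy$matrix == mx &
                                          tidy$analyte == "total"]
    expect_true(all(tot >= rel - 1e-12))
  }
  expect_true(all(tidy$concentration_ug_per_ml >= 0))
})

test_that("adaptive solution agrees with an independent fixed-step RK4 oracle", {
  t_out <- c(0.5, 1, 2, 6, 12, 24, 48, 72, 96, 120)
  s <- simulate_pbpk(mouse_model, mouse_bolus,
                     times = sort(unique(c(0, t_out))))
  y0 <- c(0, 0, 0, 0, 10, 0, 0, 0)
  ref <- oracle_rk4(y0, t_out, h = 1e-3, oracle_mouse)
  got <- s$states[match(t_out, s$times), ]
  scale <- pmax(abs(ref), 1e-8 * 10)
  expect_lt(max(abs(got - ref) / scale), 0.005)
})

test_that("solver tolerance refinement leaves reported concentrations unchanged", {
  g <- coarse_grid(48)
  s1 <- simulate_pbpk(mouse_model, mouse_bolus, g)
  s2 <- simulate_pbpk(mouse_model, mouse_bolus, g, rtol = 1e-9, atol = 1e-11)
  c1 <- s1$concentrations$concentration_ug_per_ml
  c2 <- s2$concentrations$concentration_ug_per_ml
  keep <- c2 > 1e-10
  expect_lt(max(abs(c1[keep] - c2[keep]) / c2[keep]), 0.001)
})

test_that("conjugated subsystem is linear: doubling dose doubles every X trajectory", {
  g <- coarse_grid(72)
  s1 <- simulate_pbpk(mouse_model, dose_regimen(10, "bolus"), g)
  s2 <- simulate_pbpk(mouse_model, dose_regimen(20, "bolus"), g)
  x1 <- s1$states[, c("X_b", "X_L", "X_S", "X_R")]
  x2 <- s2$states[, c("X_b", "X_L", "X_S", "X_R")]
  keep <- x1 > 1e-9
  expect_lt(max(abs(x2[keep] / x1[keep] - 2)), 1e-6)
})

test_that("with flows suppressed, release follows the closed-form exponential", {
  # near-zero circulation isolates the blood pool: X_b decays at krel_b and
  # the released pool accumulates the complement
  eps <- 1e-9
  phys <- species_physiology("isolated", BW = 0.02, V_L = 0.065, V_S = 0.005,
                             V_Nb = 0.085, Q_BL_i = eps, Q_BL_o = 2 * eps,
                             Q_BS = eps, H = 0.45, fup = 0.03, BPR = 0.84,
                             v_liver = 0.125, v_spleen = 0.016)
  rel <- released_params(V_b = 0.34, V_R = 0.1, Q_BR = 0, CL = 0,
                         Bmax_L = 49.6, KD_L = 0.6, P_L = 0.76,
                         Bmax_S = 125.9, KD_S = 0.63, P_S = 0.17)
  conj <- conjugated_params(V_NR = 0.845, N_BL = 0, N_BS = 0, N_BR = 0,
                            K_NBL = 0.9, K_NBS = 1000, krel_b = 0.125,
                            krel_L = 0.016, krel_S = 0.0063, krel_R = 0.125)
  m <- pbpk_model(phys, rel, conj)
  tt <- seq(0, 48, by = 0.5)
  s <- simulate_pbpk(m, dose_regimen(10, "bolus"), tt)
  expect_equal(unname(s$states[, "X_b"]), 10 * exp(-0.125 * tt),
               tolerance = 1e-6)
  expect_equal(unname(s$states[, "A_b"]), 10 * (1 - exp(-0.125 * tt)),
               tolerance = 1e-5)
})

test_that("total concentrations combine components per matrix", {
  phys <- mouse_model$physiology
  # zero conjugated state: blood and plasma totals equal released, while
  # tissue totals still carry the vascular contribution of released blood
  rel <- list(blood = c(1, 2), plasma = c(1.2, 2.4), liver = c(3, 1),
              spleen = c(0.5, 0.2))
  tot <- total_from_components(rel, list(X_b = c(0, 0), X_L = c(0, 0),
                                         X_S = c(0, 0)), phys)
  expect_equal(tot$blood, rel$blood)
  expect_equal(tot$plasma, rel$plasma)
  expect_equal(tot$liver, rel$liver + 0.125 * rel$blood, tolerance = 1e-12)
  expect_equal(tot$spleen, rel$spleen + 0.016 * rel$blood, tolerance = 1e-12)
  # plasma total applies the (1 - H) correction to the conjugated pool
  z <- list(blood = 0, plasma = 0, liver = 0, spleen = 0)
  tot <- total_from_components(z, list(X_b = phys$V_Nb, X_L = 0, X_S = 0),
                               phys)
  expect_equal(tot$plasma, 1 * (1 - 0.45), tolerance = 1e-12)
  # liver total = released + X_L/V_L + v_liver * C_blood_total = 3.25 here
  tot <- total_from_components(
    list(blood = 2, plasma = 0, liver = 0, spleen = 0),
    list(X_b = 0, X_L = 3 * phys$V_L, X_S = 0), phys)
  expect_equal(tot$liver, 3.25, tolerance = 1e-12)
})

test_that("constructors reject physically invalid inputs", {
  expect_error(species_physiology("x", BW = 0.02, V_L = 0.065, V_S = 0.005,
                                  V_Nb = 0.085, Q_BL_i = 5, Q_BL_o = 9.1,
                                  Q_BS = 0.74, H = 0.45, fup = 0.03,
                                  BPR = 0.84, v_liver = 0.125,
                                  v_spleen = 0.016),
               "Q_BL_i")
  expect_error(dose_regimen(-1), "positive")
  expect_error(dose_regimen(10, "infusion", 0), "duration")
  expect_error(released_params(V_b = 0.34, V_R = 0.1, Q_BR = 0.015, CL = 1,
                               Bmax_L = 49.6, KD_L = 0, P_L = 0.76,
                               Bmax_S = 125.9, KD_S = 0.63, P_S = 0.17),
               "positive")
  expect_error(set_model_param(mouse_model, list(nope = 1)), "unknown")
  expect_error(simulate_pbpk(mouse_model, mouse_bolus, c(1, 1, 2)),
               "strictly increasing")
})
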