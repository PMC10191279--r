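test_that("trapezoidal AUC handles flat, triangular and exponential profiles", {
  expect_equal(auc_trapezoid(c(0, 1), c(10, 10), "linear"), 10)
  expect_equal(auc_trapezoid(c(0, 1), c(10, 0), "linear"), 5)
  # log-down is near-exact for exponential decay; linear overestimates
  tt <- seq(0, 10, by = 0.5)
  cc <- exp(-tt)
  analytic <- 1 - exp(-10)
  expect_equal(auc_trapezoid(tt, cc), analytic, tolerance = 1e-4)
  expect_gt(auc_trapezoid(tt, cc, "linear"), analytic)
  # mixed rising/declining profile: log rule only on declining segments
  tt2 <- c(0, 1, 2, 3)
  cc2 <- c(0, 4, 2, 1)
  lin_up <- 2            # rising triangle 0 -> 4
  log_down <- (4 - 2) / log(2) + (2 - 1) / log(2)
  expect_equal(auc_trapezoid(tt2, cc2), lin_up + log_down, tolerance = 1e-12)
  expect_error(auc_trapezoid(c(1, 0), c(1, 2)), "increasing")
  expect_error(auc_trapezoid(c(0, 1), c(-1, 2)), "non-negative")
  expect_error(auc_trapezoid(0, 1), "two time points")
})

test_that("terminal half-life recovers known decay rates", {
  tt <- seq(0, 48, by = 4)
  hl <- terminal_half_life(tt, 100 * exp(-0.0693 * tt))
  expect_equal(hl$half_life, log(2) / 0.0693, tolerance = 1e-6)
  expect_equal(hl$half_life, 10.0, tolerance = 1e-2)
  expect_true(hl$reliable)
  # flat profile: zero slope, not estimable
  flat <- terminal_half_life(tt, rep(5, length(tt)))
  expect_true(is.na(flat$half_life))
  expect_false(flat$reliable)
  # biexponential sampled late: terminal phase dominates
  tb <- seq(12, 72, by = 12)
  cb <- 5 * exp(-1 * tb) + 1 * exp(-0.1 * tb)
  hlb <- terminal_half_life(tb, cb)
  expect_equal(hlb$half_life, 6.93, tolerance = 5e-3)
  # fewer than three positive points is not estimable
  expect_false(terminal_half_life(c(0, 1, 2), c(1, 0, 0))$reliable)
  # noisy profile with poor fit is flagged unreliable
  set.seed(42)
  noisy <- exp(-0.05 * tt) * exp(rnorm(length(tt), 0, 1.5))
  expect_false(terminal_half_life(tt, noisy)$reliable)
})

test_that("clearance is dose over exposure", {
  expect_equal(clearance_from_auc(10, 38.7), 0.26, tolerance = 1e-2)
  expect_equal(clearance_from_auc(50, 28), 1.786, tolerance = 5e-4)
  for (d in c(0.5, 3, 120)) expect_identical(clearance_from_auc(d, d), 1)
  expect_error(clearance_from_auc(10, 0), "positive")
  # CL * AUC = dose holds exactly for any nca() result
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 24)
  cc <- 12 * exp(-0.2 * tt)
  res <- nca(tt, cc, dose = 10)
  expect_equal(res$CL * res$AUC_last, 10, tolerance = 1e-12)
  expect_true(res$AUC_inf >= res$AUC_last)
  expect_equal(res$dose_normalized_AUC, res$AUC_last / 10, tolerance = 1e-12)
})

test_that("dose-proportionality slope is the through-origin least-squares fit", {
  # single pair degenerates to AUC/dose
  expect_equal(dose_proportionality_slope(8, 120), 15)
  # closed-form check on a small synthetic set
  d <- c(1, 2, 4)
  a <- c(3, 5, 9)
  expect_equal(dose_proportionality_slope(d, a),
               sum(d * a) / sum(d^2), tolerance = 1e-12)
  # scale equivariance: scaling the AUCs scales the slope
  expect_equal(dose_proportionality_slope(d, 10 * a),
               10 * dose_proportionality_slope(d, a), tolerance = 1e-12)
  expect_error(dose_proportionality_slope(c(0, 0), c(1, 2)), "non-zero")
})

test_that("relative exposure compares dose-normalised AUCs in percent", {
  expect_equal(relative_exposure(373 / 55, 28 / 50), 1211, tolerance = 1e-3)
  expect_equal(relative_exposure(56.3 / 12, 8.9 / 12), 633, tolerance = 1e-3)
  expect_identical(relative_exposure(2.5, 2.5), 100)
  expect_error(relative_exposure(1, 0), "positive")
})

test_that("C0 back-extrapolation is log-linear through the first two points", {
  tt <- c(0.1, 0.5, 1, 2)
  cc <- 20 * exp(-0.5 * tt)
  expect_equal(back_extrapolate_c0(tt, cc), 20, tolerance = 1e-10)
  # rising initial profile (infusion-like): no extrapolation
  expect_true(is.na(back_extrapolate_c0(c(0.1, 0.5), c(1, 2))))
})

test_that("nca_table aggregates replicate animals into composite profiles", {
  design <- default_designs(cv = 0)$mouse
  ds <- generate_dataset(design, mouse_model, seed = 7)
  tab <- nca_table(ds)
  expect_setequal(unique(tab$matrix), c("plasma", "liver", "spleen"))
  expect_setequal(unique(tab$analyte), c("released", "total"))
  expect_true(all(tab$AUC_last > 0))
  expect_equal(tab$CL * tab$AUC_last, rep(10, nrow(tab)), tolerance = 1e-12)
  # total exposure dominates released exposure in plasma
  pl <- tab[tab$matrix == "plasma", ]
  expect_gt(pl$AUC_last[pl$analyte == "total"],
            10 * pl$AUC_last[pl$analyte == "released"])
})
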