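mouse_phys <- mouse_model$physiology

test_that("blood unbound fraction is fup/BPR", {
  expect_equal(fu_blood(0.03, 0.84), 0.035714, tolerance = 1e-4)
  expect_equal(fu_blood(0.03, 0.77), 0.038961, tolerance = 1e-4)
  expect_identical(fu_blood(0.25, 1), 0.25)
  expect_error(fu_blood(0, 0.84), "positive")
  expect_error(fu_blood(0.03, -1), "positive")
})

test_that("volume scaling follows the blood-binding correction", {
  rat <- load_species_model("rat")$physiology
  human <- human_model$physiology
  ctx_rat <- scaling_context(mouse_phys, rat)
  ctx_hum <- scaling_context(mouse_phys, human)
  expect_equal(scale_volume(0.34, ctx_rat), 0.68, tolerance = 1e-10)
  expect_equal(scale_volume(0.34, ctx_rat), 0.67, tolerance = 0.02)
  expect_equal(scale_volume(0.34, ctx_hum), 0.37, tolerance = 0.005)
  # same-species context is the identity
  ctx_id <- scaling_context(mouse_phys, mouse_phys)
  expect_equal(scale_volume(0.34, ctx_id), 0.34, tolerance = 1e-12)
})

test_that("flow scaling is power-law on absolute flows", {
  rat <- load_species_model("rat")$physiology
  human <- human_model$physiology
  ctx_rat <- scaling_context(mouse_phys, rat)
  ctx_hum <- scaling_context(mouse_phys, human)
  expect_equal(scale_flow_allometric(0.015, ctx_rat), 0.00703,
               tolerance = 1e-3)
  expect_equal(scale_flow_allometric(0.015, ctx_hum), 0.0013,
               tolerance = 2e-3)
  # closed-form check against the explicit power law
  expect_equal(scale_flow_allometric(0.015, ctx_hum),
               (0.015 * 0.02) * (70 / 0.02)^0.7 / 70, tolerance = 1e-12)
  # exponent 1 leaves any per-kg flow unchanged
  ctx1 <- scaling_context(mouse_phys, human, allometric_exponent = 1)
  expect_equal(scale_flow_allometric(0.015, ctx1), 0.015, tolerance = 1e-12)
})

test_that("binding scaling applies the fu ratio and protects constants", {
  rat <- load_species_model("rat")$physiology
  dog <- dog_model$physiology
  ctx_rat <- scaling_context(mouse_phys, rat)
  ctx_dog <- scaling_context(mouse_phys, dog)
  expect_equal(scale_binding(49.6, ctx_rat, "Bmax_L"), 99.2,
               tolerance = 1e-10)
  expect_equal(scale_binding(0.9, ctx_dog, "K_NBL"), 1.559, tolerance = 1e-3)
  ctx_id <- scaling_context(mouse_phys, mouse_phys)
  expect_equal(scale_binding(0.76, ctx_id, "P_L"), 0.76, tolerance = 1e-12)
  # dissociation constants and K_NBS are cross-species constants
  expect_error(scale_binding(0.6, ctx_rat, "KD_L"), "constant")
  expect_error(scale_binding(1000, ctx_rat, "K_NBS"), "constant")
})

test_that("extravasation scales with the organ blood-flow ratio", {
  dog <- dog_model$physiology
  human <- human_model$physiology
  ctx_dog <- scaling_context(mouse_phys, dog)
  ctx_hum <- scaling_context(mouse_phys, human)
  expect_equal(scale_extravasation(2e-5, ctx_dog, "spleen"),
               2e-5 * 0.15 / 0.74, tolerance = 1e-12)
  expect_equal(scale_extravasation(2e-5, ctx_dog, "spleen"), 4.05e-6,
               tolerance = 2e-3)
  expect_equal(scale_extravasation(3e-4, ctx_hum, "liver"), 4.41e-5,
               tolerance = 1e-3)
  ctx_id <- scaling_context(mouse_phys, mouse_phys)
  expect_equal(scale_extravasation(3e-4, ctx_id, "liver"), 3e-4,
               tolerance = 1e-12)
})

test_that("scaling is compositional: the inverse ratio recovers mouse values", {
  rat <- load_species_model("rat")$physiology
  fwd <- scaling_context(mouse_phys, rat)
  bwd <- scaling_context(rat, mouse_phys)
  v <- scale_volume(scale_volume(0.34, fwd), bwd)
  expect_equal(v, 0.34, tolerance = 1e-12)
  q <- scale_flow_allometric(scale_flow_allometric(0.015, fwd), bwd)
  expect_equal(q, 0.015, tolerance = 1e-12)
  n <- scale_extravasation(scale_extravasation(2e-5, fwd, "spleen"), bwd,
                           "spleen")
  expect_equal(n, 2e-5, tolerance = 1e-12)
})

test_that("full species bundles reproduce the published drug-specific rows", {
  rat <- build_species_params("rat")
  cmp <- attr(rat, "comparison")
  expect_true(all(cmp$within))
  expect_true(all(cmp$rel_diff[cmp$parameter != "N_BL"] <= 0.05))
  # mouse-to-mouse is the identity on the fitted bundle
  mm <- build_species_params("mouse")
  expect_equal(unclass(mm$released), unclass(mouse_model$released))
  expect_equal(unclass(mm$conjugated), unclass(mouse_model$conjugated))
  # structural entries: rest volume closes the mass balance, N_BR stays 0
  hum <- suppressWarnings(build_species_params("human"))
  expect_equal(hum$conjugated$V_NR, 1 - (0.074 + 0.024 + 0.0027),
               tolerance = 1e-12)
  expect_identical(hum$conjugated$N_BR, 0)
  expect_identical(hum$conjugated$K_NBS, 1000)
  expect_identical(hum$released$KD_L, mouse_model$released$KD_L)
  # release rates and vascular fractions are never scaled
  expect_identical(hum$conjugated$krel_b, mouse_model$conjugated$krel_b)
  expect_identical(hum$physiology$v_liver, mouse_model$physiology$v_liver)
})

test_that("published dog/human rest volumes are flagged as off-rule", {
  # V_R printed for dog and human does not follow the volume rule applied
  # to every other entry; the comparison must surface this loudly
  expect_warning(build_species_params("dog"), "V_R")
  dog <- suppressWarnings(build_species_params("dog"))
  cmp <- attr(dog, "comparison")
  expect_false(cmp$within[cmp$parameter == "V_R"])
  expect_true(all(cmp$within[cmp$parameter != "V_R"]))
})
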