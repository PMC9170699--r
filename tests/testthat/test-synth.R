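test_that("generators are pure functions of their configuration", {
  cfg <- generator_config(seed = 13)
  expect_identical(gen_survival_plate(cfg), gen_survival_plate(cfg))
  expect_identical(gen_ros_plate(cfg, "kv"), gen_ros_plate(cfg, "kv"))
  expect_identical(gen_uptake_table(cfg), gen_uptake_table(cfg))
  cfg2 <- generator_config(seed = 14)
  expect_false(identical(gen_survival_plate(cfg),
                         gen_survival_plate(cfg2)))
})

test_that("the dose-scaling solver inverts the enhancement ratio", {
  cfg <- generator_config(seed = 1)
  with(cfg$materials, {
    for (i in seq_along(material)) {
      expect_equal(ner_of_k(k[i], cfg$alpha0, cfg$beta0), ner[i],
                   tolerance = 1e-12)
    }
  })
})

test_that("the plate design mirrors the experimental layout", {
  cfg <- generator_config(seed = 5)
  plate <- gen_survival_plate(cfg)
  # triplicate nanoparticle wells, sextuplicate controls, inner 24 wells
  ctrl <- plate[plate$material == "none" & plate$batch == 1 &
                  plate$dose_Gy == 0, ]
  expect_equal(nrow(ctrl), 6)
  np <- plate[plate$material == "TiO2" & plate$batch == 1 &
                plate$dose_Gy == 0, ]
  expect_equal(nrow(np), 3)
  per_plate <- plate[plate$batch == 1 & plate$dose_Gy == 0, ]
  expect_equal(nrow(per_plate), 24)
  expect_setequal(unique(plate$dose_Gy), c(0, 2, 4, 6, 8))
  q <- gen_survival_plate(cfg, design = "quench")
  expect_setequal(unique(q$dmso_M), c(0, 0.11, 0.334, 0.667, 1))
  expect_setequal(unique(q$dose_Gy), c(0, 6))
})

test_that("full DMSO saturation cancels the enhancement exactly", {
  cfg <- one_material_cfg(seed = 2, ner = 1.8, phi = 1, cv = 0)
  q <- run_survival_pipeline(gen_survival_plate(cfg, design = "quench"))
  ner1M <- q$quench$ner[q$quench$dmso_M == 1]
  expect_equal(ner1M, 1.0, tolerance = 1e-12)
  expect_equal(q$quench$dop[q$quench$dmso_M == 1], 1.0, tolerance = 1e-12)
})

test_that("a configured enhancement pair returns the matching protection", {
  # NER 2.0 without DMSO falling to 1.3 at saturation gives DoP 0.70
  cfg <- one_material_cfg(seed = 3, ner = 2.0, phi = 0.70, cv = 0)
  q <- run_survival_pipeline(gen_survival_plate(cfg, design = "quench"))
  expect_equal(q$quench$ner[q$quench$dmso_M == 0], 2.0, tolerance = 1e-12)
  expect_equal(q$quench$ner[q$quench$dmso_M == 1], 1.3, tolerance = 1e-12)
  expect_equal(q$quench$dop[q$quench$dmso_M == 1], 0.70,
               tolerance = 1e-12)
})

test_that("a zero ROS slope yields unit enhancement with a covering CI", {
  cfg <- generator_config(seed = 21,
                          ros_slopes = data.frame(material = "TiO2",
                                                  beam = "kv", slope = 0))
  a <- analyze_ros_plate(gen_ros_plate(cfg, "kv"), ci = "propagated")
  expect_equal(a$slopes$slope, 0, tolerance = 5e-5)
  expect_lte(a$slopes$ci95_lo, 0)
  expect_gte(a$slopes$ci95_hi, 0)
  expect_equal(mean(a$def_ros$def_ros), 1, tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(materials = data.frame(
    material = "X", conc_ug_mL = 1, ner = 0.5, phi = 0, lc50 = 10,
    b_tox = 0.1)), class = "radnano_domain_error")
  expect_error(generator_config(materials = data.frame(
    material = "X", conc_ug_mL = 1, ner = 1.5, phi = 2, lc50 = 10,
    b_tox = 0.1)), class = "radnano_domain_error")
  expect_error(generator_config(cv = -0.1),
               class = "radnano_domain_error")
})
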