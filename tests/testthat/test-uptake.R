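test_that("saturation fits recover noise-free truth exactly", {
  x <- c(10, 20, 40, 80, 160, 320)
  f <- fit_uptake(x, 1.2 * x^2 / (40^2 + x^2))
  expect_lt(abs(f$A - 1.2), 1e-6)
  expect_lt(abs(f$B - 40), 1e-6)
  expect_lt(abs(f$p - 2), 1e-6)
  z <- fit_uptake(x, rep(0, 6))
  expect_identical(z$A, 0)
  expect_true(z$degenerate)
  expect_error(fit_uptake(c(1, 2, 3), c(1, 2, 3)),
               class = "radnano_domain_error")
})

test_that("noisy saturation fits cover the truth at the fitted errors", {
  hits <- 0
  for (s in 1:25) {
    cfg <- generator_config(seed = s,
                            uptake = data.frame(material = "TiO2",
                                                A = 1.2, B = 40, p = 2))
    up <- gen_uptake_table(cfg)
    f <- fit_uptake(up$conc_ug_mL, up$metal_ng_total / up$cells_counted)
    if (f$converged && abs(f$A - 1.2) <= 2 * f$se["A"]) hits <- hits + 1
  }
  expect_gte(hits, 20)
})

test_that("volume fractions follow density and metal-fraction bookkeeping", {
  expect_equal(mass_to_volume_fraction(1, "Au"), 1.85, tolerance = 1e-2)
  expect_equal(mass_to_volume_fraction(1, "HfO2"), 4.35, tolerance = 1e-2)
  expect_identical(mass_to_volume_fraction(0, "Au"), 0)
  # linear in metal mass, inverse-linear in cell volume
  set.seed(6)
  for (i in 1:10) {
    m <- runif(1, 0.1, 5); k <- runif(1, 0.5, 3)
    expect_equal(mass_to_volume_fraction(k * m, "HfO2"),
                 k * mass_to_volume_fraction(m, "HfO2"))
    expect_equal(mass_to_volume_fraction(m, "HfO2", cell_volume = k * 2800),
                 mass_to_volume_fraction(m, "HfO2") / k)
  }
  # viability correction divides
  expect_equal(mass_to_volume_fraction(1, "Au", sham_viability = 0.5),
               2 * mass_to_volume_fraction(1, "Au"))
  expect_error(mass_to_volume_fraction(1, "Au", sham_viability = 0),
               class = "radnano_domain_error")
})

test_that("the uptake table analysis reproduces generator truths", {
  cfg <- generator_config(seed = 1, uptake_cv = 0)
  res <- analyze_uptake_table(gen_uptake_table(cfg))
  i <- match(res$fits$material, cfg$uptake$material)
  expect_equal(res$fits$A, cfg$uptake$A[i], tolerance = 1e-6)
  expect_equal(res$fits$B, rep(40, nrow(res$fits)), tolerance = 1e-5)
  expect_equal(res$fits$p, rep(2, nrow(res$fits)), tolerance = 1e-6)
  # tungsten uptake sits two orders of magnitude below the oxides
  expect_lt(res$fits$A[res$fits$material == "WO3"],
            res$fits$A[res$fits$material == "TiO2"] / 50)
})
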