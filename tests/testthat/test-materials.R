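test_that("BET diameter reproduces the measured reference values", {
  expect_equal(round(bet_diameter(114.0, 9.68), 1), 5.4)   # HfO2
  expect_equal(round(bet_diameter(62.7, 5.40), 1), 17.7)   # TiN
  expect_equal(round(bet_diameter(235, 4.30), 1), 5.9)     # TiO2
  expect_equal(bet_diameter(6000, 1.0), 1.0)
  # algebraic identity d * SSA * rho = 6000, and strict monotonicity
  set.seed(1)
  for (i in 1:20) {
    ssa <- runif(1, 5, 400); rho <- runif(1, 1, 20)
    expect_equal(bet_diameter(ssa, rho) * ssa * rho, 6000)
    expect_lt(bet_diameter(ssa * 1.5, rho), bet_diameter(ssa, rho))
    expect_lt(bet_diameter(ssa, rho * 1.5), bet_diameter(ssa, rho))
  }
  expect_error(bet_diameter(0, 1), class = "radnano_domain_error")
  expect_error(bet_diameter(10, -1), class = "radnano_domain_error")
})

test_that("mass/volume fraction conversions match the Au correspondence", {
  # 5 wt% Au in water is quoted as 0.26 vol%
  expect_equal(round(mass_frac_to_vol_frac(0.05, 19.3, 1.0), 4), 0.0026)
  expect_equal(mass_frac_to_vol_frac(0.05, 19.3, 1.0, "exact"),
               0.00272, tolerance = 1e-3)
  expect_identical(mass_frac_to_vol_frac(0, 5, 1, "dilute"), 0)
  expect_identical(mass_frac_to_vol_frac(0, 5, 1, "exact"), 0)
  expect_error(mass_frac_to_vol_frac(1.2, 5, 1),
               class = "radnano_domain_error")
  # exact mode round-trips through its inverse
  set.seed(2)
  for (i in 1:20) {
    wt <- runif(1); rn <- runif(1, 1, 20); rm <- runif(1, 0.5, 2)
    v <- mass_frac_to_vol_frac(wt, rn, rm, "exact")
    expect_equal(vol_frac_to_mass_frac(v, rn, rm), wt, tolerance = 1e-12)
  }
})

test_that("surface-area concentration converts linearly to mass", {
  expect_equal(surface_conc_to_mass_conc(1840, 114.0), 1614,
               tolerance = 1e-3)
  expect_identical(surface_conc_to_mass_conc(0, 235), 0)
  m <- surface_conc_to_mass_conc(1840, 62.7)
  expect_equal(m, 2934.6, tolerance = 1e-4)
  # metal content stays below 0.3 wt% in water at that mass concentration
  expect_lt(m / 1e6 * 100, 0.3)
  expect_equal(surface_conc_to_mass_conc(368, 114),
               surface_conc_to_mass_conc(1840, 114) / 5)
  expect_error(surface_conc_to_mass_conc(100, 0),
               class = "radnano_domain_error")
})

test_that("vesicle packing fraction reproduces the reference filling", {
  expect_equal(vesicle_packing_fraction(166, 50, 400), 32.4,
               tolerance = 0.05 / 32.4)
  expect_identical(vesicle_packing_fraction(0, 50, 400), 0)
  expect_equal(vesicle_packing_fraction(1, 50, 400), 100 / 512)
  expect_warning(vesicle_packing_fraction(400, 50, 400), "close-pack")
  expect_error(vesicle_packing_fraction(600, 50, 400),
               class = "radnano_domain_error")
})

test_that("sphere volume matches the reference cell volume", {
  expect_equal(sphere_volume(17.5), 2800, tolerance = 0.005)
  expect_equal(sphere_volume(6.0), 113.1, tolerance = 1e-3)
  expect_equal(sphere_volume((6 / pi)^(1 / 3)), 1)
  expect_error(sphere_volume(-1), class = "radnano_domain_error")
})

test_that("metal mass fractions come from standard atomic weights", {
  mats <- default_materials()
  expect_equal(metal_mass_fraction(mats$HfO2), 0.848, tolerance = 1e-3)
  expect_equal(metal_mass_fraction(mats$TiN), 0.774, tolerance = 1e-3)
  expect_identical(metal_mass_fraction(mats$Au), 1)
  expect_error(material_spec("X", c(Xx = 1), 5),
               class = "radnano_domain_error")
  # TiN counts only Ti as metal by default
  expect_identical(mats$TiN$metal_elements, "Ti")
})

test_that("conversions are dimensionally consistent under rescaling", {
  set.seed(3)
  for (i in 1:10) {
    k <- runif(1, 0.1, 10)
    x <- runif(1, 1, 1000); ssa <- runif(1, 10, 300)
    expect_equal(surface_conc_to_mass_conc(k * x, ssa),
                 k * surface_conc_to_mass_conc(x, ssa))
    d <- runif(1, 1, 20)
    expect_equal(sphere_volume(k * d), k^3 * sphere_volume(d))
  }
})

test_that("concentration records round-trip across bases", {
  hfo2 <- default_materials()$HfO2
  r <- concentration_record(1840, "surface_cm2_mL", hfo2)
  m <- convert_concentration(r, "mass_ug_mL")
  expect_equal(m$value, 1614, tolerance = 1e-3)
  back <- convert_concentration(m, "surface_cm2_mL")
  expect_equal(back$value, 1840, tolerance = 1e-9)
  w <- convert_concentration(m, "wt_percent")
  v <- convert_concentration(w, "vol_percent")
  expect_equal(convert_concentration(v, "mass_ug_mL")$value, m$value,
               tolerance = 1e-9)
  expect_error(concentration_record(-1, "mass_ug_mL", hfo2),
               class = "radnano_domain_error")
})
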