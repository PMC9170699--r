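test_that("spectra normalize on load and reject malformed input", {
  s <- photon_spectrum(100, 5)
  expect_identical(s$weights, 1)
  s2 <- photon_spectrum(c(50, 100), c(3, 3))
  expect_equal(s2$weights, c(0.5, 0.5))
  expect_error(photon_spectrum(c(100, 50), c(1, 1)),
               class = "radnano_format_error")
  expect_error(photon_spectrum(c(50, 100), c(1, -1)),
               class = "radnano_format_error")
  expect_error(photon_spectrum(c(0.5, 100), c(1, 1)),
               class = "radnano_format_error")
})

test_that("built-in spectra respect their design energies", {
  kv <- kv_spectrum()
  expect_lte(max(kv$energies), 150)   # tube-voltage cutoff
  expect_equal(sum(kv$weights), 1)
  mv <- mv_spectrum()
  expect_lte(max(mv$energies), 6000)
  expect_gt(sum(mv$energies * mv$weights), 500)  # MV beam is hard
})

test_that("coefficient tables interpolate log-log and never extrapolate", {
  tab <- coefficient_table("Au")
  expect_true(all(tab$mu_en_rho_cm2_g > 0))
  expect_false(is.unsorted(tab$energy_keV, strictly = TRUE))
  # K-edge jump survives interpolation (Au edge at 80.7 keV)
  expect_gt(mu_en_rho("Au", 81), mu_en_rho("Au", 80))
  expect_error(mu_en_rho("water", 1), class = "radnano_domain_error")
  expect_error(mu_en_rho("water", 2e5), class = "radnano_domain_error")
  # water reference value
  expect_equal(mu_en_rho("water", 100), 0.02546, tolerance = 1e-6)
})

test_that("macroscopic DEF obeys its algebraic identities", {
  kv <- kv_spectrum()
  expect_identical(macroscopic_def("Au", 0, kv), 1)
  expect_identical(macroscopic_def("Au", 0, kv, mode = "mixture"), 1)
  # water against itself: ratio is exactly 1
  expect_equal(macroscopic_def("water", 0.3, kv), 1.3)
  expect_equal(macroscopic_def("water", 0.3, kv, mode = "mixture"), 1)
  # monotone nondecreasing in f_mass
  f <- seq(0, 1, by = 0.1)
  d <- vapply(f, function(x) macroscopic_def("HfO2", x, kv), numeric(1))
  expect_true(all(diff(d) > 0))
  # as_printed exceeds mixture by exactly f_mass
  expect_equal(macroscopic_def("Au", 0.05, kv) -
                 macroscopic_def("Au", 0.05, kv, mode = "mixture"), 0.05)
})

test_that("spectrum-averaged coefficients order by effective Z at kV", {
  kv <- kv_spectrum()
  r <- vapply(c("Au", "HfO2", "WO3", "TiN", "TiO2", "SiO2"),
              function(m) spectrum_mean_mu(m, kv) /
                spectrum_mean_mu("water", kv), numeric(1))
  expect_gt(r["Au"], r["HfO2"])
  expect_gte(r["HfO2"], r["WO3"])
  expect_gt(r["WO3"], r["TiN"])
  # TiN carries more Ti per gram than TiO2; both far below the high-Z set
  expect_gt(r["TiN"], r["TiO2"])
  expect_gt(r["TiO2"], r["SiO2"])
})

test_that("MV averaging collapses the high-Z contrast at least fivefold", {
  kv <- kv_spectrum(); mv <- mv_spectrum()
  for (m in c("Au", "HfO2", "WO3")) {
    rkv <- spectrum_mean_mu(m, kv) / spectrum_mean_mu("water", kv)
    rmv <- spectrum_mean_mu(m, mv) / spectrum_mean_mu("water", mv)
    expect_lt(rmv, rkv / 5)
    expect_gt(rmv, 1)  # high-Z ratio stays above water at MV
  }
})

test_that("chi extraction recovers exact and noisy efficiencies", {
  ex <- chi_fit(c(1.5, 2.0, 3.0), c(0.1, 0.2, 0.4))
  expect_equal(ex$chi, 5.0)
  expect_lt(ex$ci95, 1e-10)
  expect_equal(chi_fit(c(1, 1, 1), c(0.1, 0.2, 0.4))$chi, 0)
  expect_error(chi_fit(c(1, 2), c(0, 0)), class = "radnano_domain_error")
  # seeded noisy set: true chi = 10.5 recovered within its own CI
  set.seed(41)
  fv <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  def <- 1 + 10.5 * fv + rnorm(5, 0, 0.1)
  fit <- chi_fit(def, fv)
  expect_lt(abs(fit$chi - 10.5), fit$ci95)
})

test_that("spectrum files load via the documented CSV schema", {
  p <- tempfile(fileext = ".csv")
  gen_spectrum_fixture(p)
  sp <- load_spectrum(p)
  expect_equal(sum(sp$weights), 1)
  expect_equal(sp$energies, c(30, 60, 120))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(load_spectrum(bad), class = "radnano_format_error")
})
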