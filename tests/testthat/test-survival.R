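test_that("the standard curve converts luminescence in both forms", {
  cv <- standard_curve()
  expect_identical(luminescence_to_cells(0, cv), 0)
  expect_equal(luminescence_to_cells(1e5, cv), 9723, tolerance = 1e-4)
  sat <- standard_curve(form = "saturation")
  expect_equal(luminescence_to_cells(sat$a / 2, sat), sat$b)
  expect_error(luminescence_to_cells(sat$a, sat),
               class = "radnano_domain_error")
  expect_error(standard_curve(a = 1e5, b = 2e5),
               class = "radnano_domain_error")
  # monotone in y, and inverse of the forward map
  y <- seq(0, 3e6, length.out = 7)
  expect_true(all(diff(luminescence_to_cells(y, cv)) > 0))
  expect_equal(radnano:::.cells_to_luminescence(
    luminescence_to_cells(y, cv), cv), y)
})

test_that("surviving fractions are plain unclipped ratios", {
  expect_equal(surviving_fraction(500, 1000), 0.5)
  expect_equal(surviving_fraction(1000, 1000), 1.0)
  expect_equal(surviving_fraction(1200, 1000), 1.2)  # retained, not clipped
  expect_error(surviving_fraction(1, 0), class = "radnano_domain_error")
})

test_that("generated triplicates at 4 Gy reproduce the closed-form SF", {
  cfg <- one_material_cfg(seed = 5, k = 1, alpha0 = 0.2, beta0 = 0.03,
                          cv = 0.05)
  plate <- gen_survival_plate(cfg)
  ctrl <- plate[plate$material == "none" & plate$batch == 1, ]
  cells <- luminescence_to_cells(ctrl$luminescence)
  sf4 <- mean(cells[ctrl$dose_Gy == 4]) / mean(cells[ctrl$dose_Gy == 0])
  expect_equal(sf4, exp(-1.28), tolerance = 0.08)  # 0.278 up to 5% CV noise
})

test_that("LQ fitting recovers noise-free parameters to precision", {
  d <- rep(c(0, 2, 4, 6, 8), each = 3)
  fit <- fit_lq(d, exp(-(0.2 * d + 0.03 * d^2)))
  expect_lt(abs(fit$alpha - 0.2), 1e-8)
  expect_lt(abs(fit$beta - 0.03), 1e-8)
  expect_false(fit$extrapolated)
  flat <- fit_lq(d, rep(1, length(d)))
  expect_identical(flat$alpha, 0)
  expect_identical(flat$beta, 0)
  expect_identical(flat$ld50, Inf)
  expect_true(flat$extrapolated)
  expect_error(fit_lq(c(0, 2), c(1, 0.5)), class = "radnano_domain_error")
  expect_error(fit_lq(d, rep(0, length(d))),
               class = "radnano_domain_error")
})

test_that("noisy LQ fits cover the truth at the fitted uncertainty", {
  hits <- 0
  for (s in 1:25) {
    set.seed(s)
    d <- rep(c(0, 2, 4, 6, 8), each = 3)
    sf <- exp(-(0.2 * d + 0.03 * d^2)) * rlnorm(length(d), 0, 0.1)
    fit <- fit_lq(d, sf)
    se <- sqrt(diag(fit$cov))
    if (abs(fit$alpha - 0.2) <= 2 * se[1] &&
        abs(fit$beta - 0.03) <= 2 * se[2]) hits <- hits + 1
  }
  expect_gte(hits, 20)
})

test_that("LD50 follows its closed forms and inverse identity", {
  expect_equal(ld50(log(2) / 2, 0), 2.0)
  expect_equal(ld50(0.1, 0.05), 2.855, tolerance = 1e-3)
  expect_equal(ld50(0, 0.1), sqrt(log(2) / 0.1))
  # continuity at beta -> 0
  expect_equal(ld50(0.3, 1e-12), log(2) / 0.3, tolerance = 1e-6)
  expect_error(ld50(0, 0), class = "radnano_domain_error")
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0.01, 0.5); b <- runif(1, 0, 0.1)
    D <- ld50(a, b)
    expect_equal(exp(-(a * D + b * D^2)), 0.5, tolerance = 1e-9)
  }
})

test_that("DMR is the LD50 ratio and honours dose scaling", {
  d <- rep(c(0, 2, 4, 6, 8), each = 3)
  ctrl <- fit_lq(d, exp(-(0.2 * d + 0.03 * d^2)))
  expect_equal(dmr50(ctrl, ctrl)$dmr50, 1.0)
  # dose scaling by k maps (alpha, beta) -> (k alpha, k^2 beta)
  np <- fit_lq(d, exp(-(0.4 * d + 0.12 * d^2)))
  expect_equal(dmr50(ctrl, np)$dmr50, 2.0, tolerance = 1e-7)
  flat <- fit_lq(d, rep(1, length(d)))
  r <- dmr50(flat, np)
  expect_false(r$defined)
  expect_true(is.na(r$dmr50))
})

test_that("the toxicity sigmoid yields LC50 and the inclusion flags", {
  x <- c(0, 1, 2, 3, 5)
  v <- 1 - 1 / (1 + exp(2) * exp(-1 * x))
  tf <- fit_toxicity(x, v)
  expect_equal(tf$lc50, 2, tolerance = 1e-6)
  flat <- fit_toxicity(c(0, 50, 150, 300), rep(1, 4))
  expect_identical(flat$lc50, Inf)
  expect_error(fit_toxicity(c(0, 1), c(1, 1)),
               class = "radnano_domain_error")
  # TiN-like recovery: truth 157 ug/mL within 10% through the full
  # generator + pipeline chain
  mats <- data.frame(material = "TiN", conc_ug_mL = c(20, 40, 80, 160, 320),
                     ner = 1.3, phi = 1, lc50 = 157, b_tox = 0.025)
  res <- run_survival_pipeline(
    gen_survival_plate(generator_config(seed = 3, materials = mats)))
  expect_equal(res$toxicity$lc50, 157, tolerance = 0.10)
  # the 60% cutoff excludes the concentrations whose viability is below it
  excl <- res$dmr[!res$dmr$included, ]
  expect_true(all(excl$viability < 0.60))
  incl <- res$dmr[res$dmr$included, ]
  expect_true(all(incl$viability >= 0.60))
})

test_that("NER and DoP follow their defining arithmetic", {
  expect_equal(ner(0.75, 0.375), 2.0)
  expect_equal(dop_from_ner(1.3, 2.0), 0.70, tolerance = 1e-12)
  expect_equal(dop_from_ner(1.6, 1.6), 0)
  expect_equal(dop(0.9 * 0.65, 0.9 * 0.5, 0.75, 0.375),
               dop(0.65, 0.5, 0.75, 0.375))  # common-rescaling invariance
  expect_warning(out <- dop_from_ner(1.2, 0.9), "undefined")
  expect_true(is.na(out))
  expect_error(ner(0, 0.5), class = "radnano_domain_error")
})

test_that("increasing the generator enhancement never decreases DMR", {
  ks <- c(1.2, 1.8, 2.4)
  for (s in 1:3) {
    dmrs <- vapply(ks, function(k) {
      cfg <- one_material_cfg(seed = s, k = k, cv = 0.05)
      run_survival_pipeline(gen_survival_plate(cfg))$dmr$dmr50
    }, numeric(1))
    expect_true(all(diff(dmrs) > 0))
  }
})
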