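test_that("water nanoparticles give DEF identically 1 (correlated null)", {
  kv <- kv_spectrum()
  g <- build_vesicle_geometry(166, seed = 1)
  s <- simulate_vesicle(g, "water", kv, 5e3, seed = 3)
  expect_true(all(abs(s$def[!is.na(s$def)] - 1) < 1e-12))
  gc1 <- build_cell_geometry(2, seed = 2)
  sc <- simulate_cell(gc1, "water", kv, 5e3, seed = 3)
  expect_true(all(abs(sc$def[!is.na(sc$def)] - 1) < 1e-12))
})

test_that("identical seed, geometry and histories give identical scores", {
  kv <- kv_spectrum()
  g <- build_vesicle_geometry(40, seed = 5)
  a <- simulate_vesicle(g, "Au", kv, 5e3, seed = 11)
  b <- simulate_vesicle(g, "Au", kv, 5e3, seed = 11)
  expect_identical(a$def, b$def)
  expect_identical(a$energy_eV, b$energy_eV)
  c2 <- simulate_vesicle(g, "Au", kv, 5e3, seed = 12)
  expect_false(identical(a$def, c2$def))
})

test_that("every interaction deposits exactly the photon energy", {
  # the electron mode only redistributes energy in space: totals agree
  kv <- kv_spectrum()
  g <- build_vesicle_geometry(40, seed = 5)
  loc <- simulate_vesicle(g, "HfO2", kv, 5e3, seed = 9,
                          electron_mode = "local")
  csd <- simulate_vesicle(g, "HfO2", kv, 5e3, seed = 9,
                          electron_mode = "csda")
  expect_equal(sum(loc$energy_eV), sum(csd$energy_eV), tolerance = 1e-9)
})

test_that("local-deposition homogeneous run matches the mixture rule", {
  kv <- kv_spectrum()
  h <- simulate_homogeneous("Au", 0.05, kv, 1e5, seed = 2)
  target <- macroscopic_def("Au", 0.05, kv, mode = "mixture")
  expect_lt(abs(h$def - target), 3 * h$se)
})

test_that("shell enhancement decays monotonically away from the vesicle", {
  kv <- kv_spectrum()
  g <- build_vesicle_geometry(166, seed = 1)
  s <- simulate_vesicle(g, "Au", kv, 5e4, seed = 3, replicates = 3)
  ex <- s$def[grep("shell", s$compartment)] - 1
  expect_true(all(ex > 0))
  expect_true(all(diff(ex) <= 0))
  # and the in-vesicle water enhancement dominates every shell
  expect_gt(s$def[s$compartment == "vesicle"], max(ex) + 1)
})

test_that("cytoplasm enhancement dominates nuclear enhancement", {
  kv <- kv_spectrum()
  g <- build_cell_geometry(3, seed = 2)
  for (m in c("Au", "HfO2")) {
    s <- simulate_cell(g, m, kv, 2e4, seed = 7)
    cyt <- s$def[s$compartment == "cytoplasm"]
    nuc <- s$def[s$compartment == "nucleus"]
    expect_gte(cyt, nuc)
    expect_gt(nuc, 1)
  }
})

test_that("replicate spread contracts roughly as one over root histories", {
  kv <- kv_spectrum()
  g <- build_vesicle_geometry(40, seed = 5)
  hist_grid <- c(1e3, 1e4, 1e5)
  sds <- vapply(hist_grid, function(nh) {
    defs <- vapply(0:3, function(i) {
      s <- simulate_vesicle(g, "Au", kv, nh, seed = 100 + i)
      s$def[s$compartment == "vesicle"]
    }, numeric(1))
    sd(defs)
  }, numeric(1))
  slope <- coef(lm(log10(sds) ~ log10(hist_grid)))[2]
  expect_lt(slope, -0.2)
  expect_gt(slope, -0.8)
})

test_that("history and replicate accounting is reported, not hidden", {
  kv <- kv_spectrum()
  g <- build_vesicle_geometry(20, seed = 4)
  s <- simulate_vesicle(g, "Au", kv, 2e3, seed = 6, replicates = 2)
  expect_identical(attr(s, "n_histories"), 2e3)
  expect_identical(attr(s, "replicates"), 2)
  expect_true(all(is.finite(s$def_sd[!is.na(s$def)])))
  expect_error(simulate_vesicle(g, "Au", kv, 100, seed = 1),
               class = "radnano_domain_error")
})
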