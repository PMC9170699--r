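test_that("vesicle geometry reproduces its packing fraction exactly", {
  g <- build_vesicle_geometry(166, seed = 1)
  expect_equal(g$packing_vol_percent, 166 * (50 / 400)^3 * 100,
               tolerance = 1e-12)
  expect_equal(nrow(g$np_centers), 166)
  g0 <- build_vesicle_geometry(0, seed = 1)
  expect_equal(nrow(g0$np_centers), 0)
})

test_that("sphere placement is reproducible, non-overlapping and inside", {
  for (s in c(1, 7, 23)) {
    for (n in c(20, 166)) {       # dart-throwing and lattice regimes
      g <- build_vesicle_geometry(n, seed = s)
      C <- g$np_centers
      expect_identical(C, build_vesicle_geometry(n, seed = s)$np_centers)
      r <- sqrt(rowSums(C^2))
      expect_true(all(r <= 200 - 25 + 1e-9))
      if (n > 1) {
        dd <- as.matrix(dist(C))
        expect_gte(min(dd[upper.tri(dd)]), 50 - 1e-9)
      }
    }
  }
})

test_that("impossible packings are rejected", {
  expect_error(build_vesicle_geometry(600, seed = 1),
               class = "radnano_domain_error")
})

test_that("cell geometry enforces compartment containment", {
  g <- build_cell_geometry(10, seed = 2)
  rad <- sqrt(rowSums(g$vesicle_centers^2))
  expect_true(all(rad >= g$nucleus_radius + g$vesicle_radius))
  expect_true(all(rad <= g$cell_radius - g$vesicle_radius))
  # explicit placements violating the constraints are errors
  expect_error(build_cell_geometry(1, seed = 1,
                                   vesicle_centers = matrix(c(1.5, 0, 0),
                                                            1)),
               class = "radnano_domain_error")   # touches the nucleus
  expect_error(build_cell_geometry(1, seed = 1,
                                   vesicle_centers = matrix(c(2.95, 0, 0),
                                                            1)),
               class = "radnano_domain_error")   # pokes out of the cell
  expect_error(build_cell_geometry(2, seed = 1,
                                   vesicle_centers = rbind(c(2.2, 0, 0),
                                                           c(2.3, 0, 0))),
               class = "radnano_domain_error")   # vesicles overlap
})
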