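test_that("DEF_ROS is the ratio of radiation-induced gains", {
  expect_equal(def_ros(500, 100, 300, 100), 2.0)
  expect_equal(def_ros(300, 100, 300, 100), 1.0)
  expect_equal(def_ros(350, 150, 300, 100), 1.0)  # equal net gains
  expect_error(def_ros(500, 100, 100, 100), class = "radnano_domain_error")
  # invariance under a common fluorometer gain rescaling
  k <- 3.7
  expect_equal(def_ros(k * 500, k * 100, k * 300, k * 100),
               def_ros(500, 100, 300, 100))
})

test_that("the slope regression is anchored at DEF_ROS = 1", {
  sa <- rep(c(36.8, 368, 1840), each = 6)
  s <- ros_slope(1 + 0.002 * sa, sa)
  expect_equal(s$slope, 0.002)
  expect_lt(s$ci95_hi - s$ci95_lo, 1e-12)
  expect_equal(ros_slope(rep(1, 18), sa)$slope, 0)
  expect_error(ros_slope(c(1, 2), c(10, 10)),
               class = "radnano_domain_error")
  # free-intercept variant reduces to lm; DEF at zero surface is 1.2 here
  sf <- suppressWarnings(ros_slope(1.2 + 0.002 * sa, sa,
                                   free_intercept = TRUE))
  expect_equal(sf$slope, 0.002, tolerance = 1e-9)
  expect_equal(sf$intercept, 1.2, tolerance = 1e-9)
})

test_that("a zero-noise plate returns the configured truth exactly", {
  cfg <- generator_config(seed = 2, cv = 0)
  a <- suppressWarnings(analyze_ros_plate(gen_ros_plate(cfg, "kv"),
                                          ci = "residual"))
  truth <- cfg$ros_slopes[cfg$ros_slopes$beam == "kv", ]
  m <- merge(a$slopes, truth, by = "material")
  expect_equal(m$slope.x, m$slope.y, tolerance = 1e-12)
  expect_equal(unique(a$slopes$n), 18)  # 3 levels x 6 replicates
})

test_that("gold wells trigger the assay-interference warning", {
  cfg <- generator_config(seed = 2, cv = 0)
  ros <- gen_ros_plate(cfg, "kv")
  ros$material[ros$material == "TiO2"] <- "Au"
  expect_warning(analyze_ros_plate(ros, ci = "residual"), "interference")
})

test_that("the kV efficiency ordering is recovered at default noise", {
  ok <- 0
  for (s in 1:20) {
    cfg <- generator_config(seed = s)
    a <- suppressWarnings(analyze_ros_plate(gen_ros_plate(cfg, "kv"),
                                            ci = "residual"))
    sl <- a$slopes
    if (sl$slope[sl$material == "WO3"] > sl$slope[sl$material == "TiO2"] &&
        sl$slope[sl$material == "TiO2"] >
          sl$slope[sl$material == "HfO2"]) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("propagated and bootstrap intervals widen over the naive one", {
  # all DEF_ROS values share the blank denominator; intervals that
  # propagate it must not be narrower than the residual interval
  cfg <- generator_config(seed = 9, cv = 0.10,
                          ros_slopes = data.frame(material = "TiO2",
                                                  beam = "kv",
                                                  slope = 1e-3))
  plate <- gen_ros_plate(cfg, "kv")
  res <- analyze_ros_plate(plate, ci = "residual")$slopes
  prop <- analyze_ros_plate(plate, ci = "propagated")$slopes
  set.seed(1)
  boot <- analyze_ros_plate(plate, ci = "bootstrap", n_boot = 400)$slopes
  w <- function(d) d$ci95_hi - d$ci95_lo
  expect_gt(w(prop), w(res))
  expect_gt(w(boot), w(res) * 0.8)
  expect_equal(prop$slope, res$slope)   # the point estimate is unchanged
})
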