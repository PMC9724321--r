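test_that("angular eccentricity spans sphere to needle", {
  expect_equal(angular_eccentricity(1, 1), 0)
  expect_equal(angular_eccentricity(1, 2), acos(0.5))
  expect_equal(angular_eccentricity(1, 2), 1.0472, tolerance = 1e-4)
  # canonicalization sorts the axes; disabling it makes a > b a domain error
  expect_equal(angular_eccentricity(2, 1), acos(0.5))
  expect_error(angular_eccentricity(2, 1, canonicalize = FALSE), "domain")
  expect_error(angular_eccentricity(0, 1), "positive")
})

test_that("surface area has the correct sphere limit and hand value", {
  expect_equal(spheroid_surface_area(1, 1), 4 * pi, tolerance = 1e-12)
  expect_equal(spheroid_surface_area(1, 2),
               2 * pi * (1 + 2 * (pi / 3) / sin(pi / 3)), tolerance = 1e-12)
  expect_equal(spheroid_surface_area(1, 2), 21.48, tolerance = 1e-3)
  # near-sphere path goes through the removable singularity smoothly
  expect_equal(spheroid_surface_area(1, 1 + 1e-12), 4 * pi, tolerance = 1e-9)
  # r^2 scaling for spheres
  expect_equal(spheroid_surface_area(3, 3), 9 * spheroid_surface_area(1, 1))
})

test_that("surface area equals the classical prolate closed form", {
  set.seed(99)
  a <- runif(1000, 0.2, 5)
  b <- a * runif(1000, 1, 4)
  got <- spheroid_surface_area(a, b, canonicalize = FALSE)
  e <- sqrt(1 - a^2 / b^2)
  classical <- 2 * pi * a^2 + 2 * pi * a * b * asin(e) / e
  expect_equal(got, classical, tolerance = 1e-9)
})

test_that("volume supports both the a*b^2 and the textbook a^2*b forms", {
  expect_equal(spheroid_volume(1, 1), 4 * pi / 3)
  expect_equal(spheroid_volume(1, 1, mode = "a2b"), 4 * pi / 3)
  expect_equal(spheroid_volume(1, 2), 4 / 3 * pi * 4)
  expect_equal(spheroid_volume(1, 2, mode = "a2b"), 4 / 3 * pi * 2)
  expect_equal(spheroid_volume(1e-12, 2), 0, tolerance = 1e-9)
  # strictly increasing in each axis (both modes)
  for (m in c("ab2", "a2b")) {
    expect_gt(spheroid_volume(1.1, 2, mode = m), spheroid_volume(1, 2, mode = m))
    expect_gt(spheroid_volume(1, 2.1, mode = m), spheroid_volume(1, 2, mode = m))
  }
  expect_error(spheroid_volume(-1, 2), "positive")
})

test_that("surface area is strictly increasing in each axis", {
  expect_gt(spheroid_surface_area(1.1, 2), spheroid_surface_area(1, 2))
  expect_gt(spheroid_surface_area(1, 2.1), spheroid_surface_area(1, 2))
})

test_that("percent volume change matches its definition", {
  expect_equal(percent_volume_change(5, 5), 0)
  expect_equal(percent_volume_change(1.66 * 3, 3), 66, tolerance = 1e-12)
  expect_equal(percent_volume_change(0.36 * 3, 3), -64, tolerance = 1e-12)
  expect_error(percent_volume_change(1, 0), "v_ref")
})

test_that("per-cell metrics canonicalize measured axes to semi-axes", {
  meas <- data.frame(cell_id = c("c1", "c2"), condition = "seed",
                     major_axis_um = c(4, 2),   # c2 recorded swapped
                     minor_axis_um = c(2, 4))
  m <- cell_shape_metrics(meas)
  expect_equal(m$a_um, c(1, 1))
  expect_equal(m$b_um, c(2, 2))
  expect_equal(m$volume_um3, rep(4 / 3 * pi * 4, 2))
  expect_true(all(m$surface_area_um2 >= 4 * pi * m$a_um^2))
  expect_error(cell_shape_metrics(data.frame(cell_id = 1)), "columns")
})

test_that("population summaries and volume changes aggregate correctly", {
  meas <- rbind(
    simulate_cell_dimensions(2, 2.6, cv = 0, n = 2, condition = "seed"),
    simulate_cell_dimensions(2.4, 3.0, cv = 0, n = 1, condition = "stressed")
  )
  m <- cell_shape_metrics(meas)
  s <- summarize_population(m, reference = "seed")
  expect_equal(s$n, c(2, 1))
  expect_equal(s$sd_volume_um3, c(0, NA_real_))  # identical pair; single cell
  expect_equal(s$volume_change_pct[s$condition == "seed"], 0)
  want <- percent_volume_change(spheroid_volume(2.4, 3.0), spheroid_volume(2, 2.6))
  expect_equal(s$volume_change_pct[s$condition == "stressed"], want)
  expect_error(summarize_population(m[0, ]), "insufficient")
  expect_error(summarize_population(m, reference = "nope"), "not present")
})

test_that("simulated populations recover their target mean volume", {
  meas <- simulate_cell_dimensions(2, 2.6, cv = 0.1, n = 100,
                                   condition = "seed", seed = 5)
  m <- cell_shape_metrics(meas)
  s <- summarize_population(m)
  # E[a b^2] for independent log-normals: mean_a * mean_b^2 * (1 + cv^2)
  truth <- 4 / 3 * pi * 2 * 2.6^2 * (1 + 0.01)
  se <- s$sd_volume_um3 / sqrt(s$n)
  expect_lt(abs(s$mean_volume_um3 - truth), 3 * se)
})
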