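test_that("liquid density follows the linear sugar correlation", {
  expect_equal(liquid_density(0, 0, 0), 0.97)
  expect_equal(liquid_density(0.10), 1.0156)
  expect_equal(liquid_density(0.05, 0.01, 0.02), 1.00648)
  # strictly increasing in each sugar
  base <- liquid_density(0.02, 0.02, 0.02)
  expect_gt(liquid_density(0.03, 0.02, 0.02), base)
  expect_gt(liquid_density(0.02, 0.03, 0.02), base)
  expect_gt(liquid_density(0.02, 0.02, 0.03), base)
  expect_error(liquid_density(-0.01), "c_glucose")
  expect_error(liquid_density(0, -1e-6), "c_cellobiose")
})

test_that("insoluble solids fraction responds to solubilized mass", {
  # no solubilization: identity at any density
  for (rho in c(0.8, 0.97, 1.2)) {
    expect_identical(insoluble_solids_fraction(0.13, rho_l = rho), 0.13)
  }
  expect_equal(insoluble_solids_fraction(0.13, d_glucose = 0.05, rho_l = 1.0),
               (0.13 - 0.05 / 1.11) / (1 - 0.05 / 1.11))
  expect_equal(insoluble_solids_fraction(0.13, d_glucose = 0.05, rho_l = 1.0),
               0.0889623, tolerance = 1e-6)
  # numerator zero at complete solubilization
  expect_equal(insoluble_solids_fraction(0.05 / 1.11, d_glucose = 0.05,
                                         rho_l = 1.0), 0)
  # strictly decreasing in total solubilized mass
  s1 <- insoluble_solids_fraction(0.2, d_ethanol = 0.01, rho_l = 1.0)
  s2 <- insoluble_solids_fraction(0.2, d_ethanol = 0.02, rho_l = 1.0)
  expect_lt(s2, s1)
  expect_error(insoluble_solids_fraction(1.0, rho_l = 1.0), "\\[0, 1\\)")
  expect_error(insoluble_solids_fraction(0.1, d_glucose = 1.2, rho_l = 1.0),
               "degenerate")
})

test_that("liquid volume partitions system mass by solids fraction", {
  expect_equal(liquid_volume(100, 0.13, 1.0), 87)
  expect_equal(liquid_volume(97, 0, 0.97), 100)
  expect_equal(liquid_volume(100, 1.0, 1.0), 0)
  expect_error(liquid_volume(100, 0.1, 0), "rho_l")
  expect_error(liquid_volume(0, 0.1, 1), "m_total")
})

test_that("yield and conversion equations match hand-evaluated values", {
  expect_equal(glucose_yield(0, 50, 5), 0)
  # stoichiometric maximum: C_g * V_l == 1.11 * M_g
  expect_equal(glucose_yield(1.11 * 9 / 100, 100, 9), 100)
  expect_equal(glucose_yield(0.05, 100, 9.0), 50.05005, tolerance = 1e-7)

  expect_equal(glucan_conversion(v_liquid = 50, m_glucan = 5), 0)
  expect_equal(glucan_conversion(c_ethanol = 0.567 * 5 / 50, v_liquid = 50,
                                 m_glucan = 5), 100)
  expect_equal(glucan_conversion(c_glucose = 0.0222, c_ethanol = 0.0567,
                                 v_liquid = 100, m_glucan = 14),
               (2 + 10) / 14 * 100, tolerance = 1e-12)

  expect_equal(theoretical_ethanol_yield(0, 25, 4.5), 0)
  expect_equal(theoretical_ethanol_yield((0.51 / 0.9) * 4.5 / 25, 25, 4.5), 100)
  expect_equal(theoretical_ethanol_yield(0.08, 25, 4.5), 78.43137,
               tolerance = 1e-7)
  expect_error(theoretical_ethanol_yield(0.05, 25, 0), "m_glucan")
})

test_that("ethanol-only conversion and theoretical yield agree to the factor rounding", {
  # 0.567 (conversion) vs 0.51/0.9 = 0.5667 (theoretical yield): < 0.3% apart
  ceth <- runif(20, 0.001, 0.09)
  conv <- glucan_conversion(c_ethanol = ceth, v_liquid = 40, m_glucan = 5)
  thy <- theoretical_ethanol_yield(ceth, 40, 5)
  expect_true(all(abs(conv - thy) / thy < 0.003))
})

test_that("ethanol yield is linear in ethanol concentration at fixed volume", {
  y1 <- theoretical_ethanol_yield(0.02, 80, 6)
  y3 <- theoretical_ethanol_yield(0.06, 80, 6)
  expect_equal(y3, 3 * y1)
})

test_that("glucan-equivalent loading maps solids loadings to glucan loadings", {
  m <- glucan_equivalent_loading(c(17, 20, 10), c(0.885, 0.885, 1.0))
  expect_equal(m$glucan_wt_pct_rounded, c(15, 18, 10))
  expect_equal(m$glucan_wt_pct, c(15.045, 17.7, 10))
  expect_error(glucan_equivalent_loading(101, 0.5), "solids_wt_pct")
  expect_error(glucan_equivalent_loading(10, 1.5), "glucan_fraction")
})

test_that("productivities follow their definitions", {
  expect_equal(ssf_productivity(0, 10, 2), 0)
  expect_equal(ssf_productivity(2.775, 10, 2), 0.125)
  expect_equal(ssf_productivity(2.775, 10, 4), 0.0625)  # doubling time halves
  expect_error(ssf_productivity(1, 10, 0), "elapsed_days")

  expect_equal(sugar_productivity(0, 10, 8), 0)
  expect_equal(sugar_productivity(4, 10, 8), 0.05)
  expect_equal(sugar_productivity(8, 10, 8), 0.10)  # linear in ethanol
  expect_error(sugar_productivity(1, 0, 8), "glucose_fed_g")
})
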