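test_that("water balance step handles identity and the one-layer bucket", {
  p <- flat_profile()
  st <- soil_water_state(p)
  out <- step_water_balance(p, st, 0, 0, 0)
  expect_equal(out$sw, st$sw)
  # one layer, 10 mm of rain fills the dul -> sat pore space exactly
  p1 <- soil_profile(100, 0.2, 0.3, 0.4, ks = 0)
  s1 <- soil_water_state(p1, sw = 0.3)
  o1 <- step_water_balance(p1, s1, 10)
  expect_equal(o1$sw, 0.4)
  expect_equal(o1$cum_runoff, 0)
  expect_equal(o1$cum_drainage, 0)
  expect_error(step_water_balance(p1, s1, -1), "non-negative")
})

test_that("every step conserves water to 1e-6 mm (brute-force ledger)", {
  p <- flat_profile()
  set.seed(101)
  for (rep in 1:50) {
    sw0 <- runif(4, p$ll15, p$sat)
    st <- soil_water_state(p, sw = sw0)
    rain <- runif(1, 0, 60)
    evap <- runif(1, 0, 3)
    tr <- pmin(runif(4, 0, 1.5), pmax(0, (sw0 - p$ll15) * p$thickness))
    out <- step_water_balance(p, st, rain, evap, tr)
    lhs <- rain - out$cum_runoff - out$cum_drainage - out$cum_evap -
      out$cum_transp
    rhs <- sum(out$sw * p$thickness) - sum(sw0 * p$thickness)
    expect_lt(abs(lhs - rhs), 1e-6)
    expect_true(all(out$sw <= p$sat + 1e-9))
    expect_true(all(out$sw >= p$ll15 - 1e-4 - 1e-9))
  }
})

test_that("the water table is the bottom-anchored saturated block", {
  p <- flat_profile(n = 4, thickness = 300)
  expect_equal(water_table_depth(p, soil_water_state(p, sw = p$sat)), 0)
  expect_equal(water_table_depth(p, soil_water_state(p, sw = p$dul)), 1200)
  st <- soil_water_state(p, sw = c(0.30, 0.30, 0.40, 0.40))
  expect_equal(water_table_depth(p, st), 600)
})

test_that("forced flooding saturates, is idempotent, and logs its water", {
  p <- flat_profile()
  st <- soil_water_state(p)  # at dul
  f1 <- force_flood(p, st)
  expect_equal(water_table_depth(p, f1), 0)
  expect_equal(f1$cum_flood_water, sum(p$thickness * (p$sat - p$dul)))
  f2 <- force_flood(p, f1)
  expect_equal(f2$sw, f1$sw)
  expect_equal(f2$cum_flood_water, f1$cum_flood_water)
})

test_that("root submergence fraction is the clamped linear formula", {
  expect_equal(fraction_roots_submerged(1000, 0), 1)
  expect_equal(fraction_roots_submerged(1000, 1500), 0)
  expect_equal(fraction_roots_submerged(1000, 200), 0.8)
  expect_error(fraction_roots_submerged(0, 100), "positive")
})

test_that("nodule-zone WFPS excess hits its anchors and weights by depth", {
  p <- soil_profile(c(225, 225, 300), 0.15, 0.30, 0.40)
  expect_equal(wfps_excess_fraction(p, soil_water_state(p, sw = p$dul)), 0)
  expect_equal(wfps_excess_fraction(p, soil_water_state(p, sw = p$sat)), 1)
  st <- soil_water_state(p, sw = c(0.30, 0.40, 0.30))
  expect_equal(wfps_excess_fraction(p, st, 450), 0.5)
  expect_error(wfps_excess_fraction(p, st, -10), "positive")
})

test_that("root-zone supply excludes saturated layers", {
  p <- flat_profile()
  expect_equal(available_supply(p, soil_water_state(p, sw = p$sat), 1200), 0)
  expect_equal(available_supply(p, soil_water_state(p, sw = p$ll15), 1200), 0)
  p1 <- soil_profile(300, 0.20, 0.35, 0.45, ks = 10, kl = 0.10)
  expect_equal(available_supply(p1, soil_water_state(p1, sw = 0.30), 300), 3)
})

test_that("air-filled porosity reads the layer containing the depth", {
  p <- soil_profile(c(300, 300), 0.2, 0.35, 0.45)
  expect_equal(air_filled_porosity_at(p, soil_water_state(p, sw = 0.45), 100), 0)
  expect_equal(air_filled_porosity_at(p, soil_water_state(p, sw = 0.42), 100),
               0.03)
  expect_equal(air_filled_porosity_at(p, soil_water_state(p, sw = 0.30), 500),
               0.15)
  expect_error(air_filled_porosity_at(p, soil_water_state(p), 700), "outside")
})

test_that("waterlogging predictors are monotone in stored water", {
  p <- flat_profile()
  set.seed(55)
  for (rep in 1:20) {
    a <- runif(1)
    b <- runif(1, a, 1)  # wetter state dominates layer-wise
    swa <- p$ll15 + a * (p$sat - p$ll15)
    swb <- p$ll15 + b * (p$sat - p$ll15)
    sa <- soil_water_state(p, sw = swa)
    sb <- soil_water_state(p, sw = swb)
    expect_gte(wfps_excess_fraction(p, sb), wfps_excess_fraction(p, sa))
    expect_gte(fraction_roots_submerged(900, water_table_depth(p, sb)),
               fraction_roots_submerged(900, water_table_depth(p, sa)))
  }
})

test_that("soil profiles reject inverted water constants", {
  expect_error(soil_profile(300, 0.3, 0.25, 0.4), "ll15 < dul < sat")
  expect_error(soil_profile(-10, 0.1, 0.2, 0.3), "thickness")
})
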