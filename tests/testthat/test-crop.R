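test_that("daily thermal time caps at the optimum and floors at base", {
  expect_equal(daily_thermal_time(12, 8, 10, 30), 0)
  expect_equal(daily_thermal_time(30, 20, 10, 30), 15)
  expect_equal(daily_thermal_time(40, 36, 10, 30), 20)
  expect_error(daily_thermal_time(10, 20, 10, 30), "tmax")
})

test_that("phenology advances with thermal time and stalls at multiplier 0", {
  cv <- cultivar()
  st <- crop_state()
  frozen <- advance_phenology(st, 50, 0, cv)
  expect_equal(frozen$stage_code, st$stage_code)
  expect_equal(frozen$cum_tt, 0)
  adv <- advance_phenology(st, cv$tt_targets[["sow_emerge"]] + 1, 1, cv)
  expect_gte(adv$stage_code, 1)
  expect_error(advance_phenology(st, 10, 1.4, cv), "0, 1")
})

test_that("interception follows Beer's law", {
  expect_equal(intercepted_radiation(20, 0, 0.5), 0)
  expect_equal(intercepted_radiation(20, 1e4, 0.5), 20)
  expect_equal(intercepted_radiation(20, 2, 0.5), 20 * (1 - exp(-1)),
               tolerance = 1e-10)
})

test_that("growth converts radiation with the binding stress multiplier", {
  expect_equal(daily_growth(10, 1.1, 0, 1), 0)
  expect_equal(daily_growth(10, 1.1, 1, 1), 110)
  expect_equal(daily_growth(10, 1.0, 0.6, 0.8), 60)
  expect_error(daily_growth(10, 1, 1.2, 1), "0, 1")
})

test_that("transpiration demand is VPD-normalised potential growth", {
  expect_equal(transpiration_demand(0, 0.005, 1.5), 0)
  expect_equal(transpiration_demand(11, 0.005, 1.5), 3.3)
  expect_equal(transpiration_demand(11, 0.005, 3.0),
               2 * transpiration_demand(11, 0.005, 1.5))
  expect_error(transpiration_demand(10, 0.005, 0), "vpd")
})

test_that("roots stop at 3% air-filled porosity and at their maximum", {
  cv <- cultivar(root_elong_rate = 25, max_root_depth = 1000)
  p <- soil_profile(rep(300, 4), 0.2, 0.35, 0.45)
  st <- crop_state(root_depth_init = 500)
  st$stage_code <- 2
  wet <- soil_water_state(p, sw = 0.43)   # AFP 0.02 at the front
  expect_equal(root_growth(st, p, wet, cv), 500)
  dry <- soil_water_state(p, sw = 0.35)   # AFP 0.10
  expect_equal(root_growth(st, p, dry, cv), 525)
  st$root_depth <- 1000
  expect_equal(root_growth(st, p, dry, cv), 1000)
})

test_that("soil N is taken before fixation and the ratio clamps", {
  cv <- cultivar(potential_fix_rate = 1, max_n_uptake_rate = 5)
  r <- n_uptake_and_fixation(2.0, 1.5, 1, 4.5, cv)  # fixation plateau
  expect_equal(r$uptake, 1.5)
  expect_equal(r$fixed, 0.5)
  expect_equal(r$n_stress_multiplier, 1)
  r0 <- n_uptake_and_fixation(2.0, 0, 0, 4.5, cv)
  expect_equal(r0$fixed, 0)
  expect_equal(r0$n_stress_multiplier, 0)
  expect_equal(n_uptake_and_fixation(0, 3, 1, 4.5, cv)$n_stress_multiplier, 1)
  expect_error(n_uptake_and_fixation(-1, 0, 1, 2, cv), "non-negative")
})

test_that("the fixation capacity curve ramps to the pod-fill plateau", {
  cv <- cultivar(potential_fix_rate = 4, max_n_uptake_rate = 5)
  fix_at <- function(stage) n_uptake_and_fixation(10, 0, 1, stage, cv)$fixed
  expect_equal(fix_at(1), 0)
  expect_lt(fix_at(2.5), fix_at(4))
  expect_equal(fix_at(4), 4)
  expect_equal(fix_at(5), 4)
})

test_that("grain fills only after R3 and never exceeds its pod sink", {
  cv <- cultivar()
  st <- crop_state()
  st$stage_code <- 3.5
  st$biomass <- 5000
  st$pod_capacity <- 3000
  expect_equal(grain_fill(st, 100, cv)$grain, 0)
  st$stage_code <- 4.5
  g1 <- grain_fill(st, 100, cv)
  expect_equal(g1$grain, cv$grain_fill_fraction * 100)
  st$grain <- 2990
  expect_equal(grain_fill(st, 1000, cv)$grain, 3000)  # sink-capped
  st$grain <- 0
  st$stage_code <- 5.5
  expect_equal(grain_fill(st, 0, cv)$grain, 0.002 * 5000)
  st$biomass <- 0
  st$grain <- 0
  expect_equal(grain_fill(st, 0, cv)$grain, 0)
})

test_that("pod capacity accrues in the R1-R5 window and aborts when starved", {
  cv <- cultivar(pod_set_coeff = 0.8, abort_rate = 0.1, abort_threshold = 0.5)
  st <- crop_state()
  st$stage_code <- 2
  expect_equal(update_pod_capacity(st, 100, 1, cv)$pod_capacity, 0)
  st$stage_code <- 3.5
  st <- update_pod_capacity(st, 100, 1, cv)
  expect_equal(st$pod_capacity, 80)
  starved <- update_pod_capacity(st, 0, 0, cv)
  expect_equal(starved$pod_capacity, 80 * 0.9)
  expect_equal(starved$pod_abort, 0.9)
  # subsequent accrual is also depressed
  st2 <- update_pod_capacity(starved, 100, 1, cv)
  expect_equal(st2$pod_capacity, 80 * 0.9 + 80 * 0.9)
})

test_that("maturity-group presets order season length correctly", {
  tt3 <- sum(cultivar_preset(3)$tt_targets)
  tt5 <- sum(cultivar_preset(5)$tt_targets)
  expect_lt(tt3, tt5)
  expect_error(cultivar_preset(7), "preset")
  expect_error(cultivar(maturity_group = 2), "maturity_group")
})
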