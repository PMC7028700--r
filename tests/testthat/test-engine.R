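test_that("a season run is deterministic and internally consistent", {
  cfg <- det_config()
  a <- run_season(cfg)
  b <- run_season(cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(a$yield, b$yield)
  tr <- a$trace
  expect_false(a$truncated)
  expect_equal(a$yield, tail(tr$grain, 1))
  expect_equal(a$biomass, tail(tr$biomass, 1))
  expect_true(all(diff(tr$stage) >= 0))
  expect_true(all(diff(tr$biomass) >= 0))
  expect_true(all(tr$grain <= tr$biomass))
  expect_gt(a$yield, 0)
})

test_that("a zero-duration treatment is the control", {
  cfg <- det_config(treatments = list(flood_treatment("V4", duration_days = 0)))
  ctrl <- det_config()
  expect_equal(run_season(cfg)$yield, run_season(ctrl)$yield)
})

test_that("water and N ledgers close over a flooded season", {
  cfg <- det_config(treatments = list(flood_treatment("R2",
                                                      duration_days = 7)))
  r <- run_season(cfg)
  expect_lt(abs(r$water_balance$closure), 1e-3)
  expect_gt(r$water_balance$flood_water, 0)
  # plant N equals its two sources (a small seed reserve counts as uptake)
  expect_equal(r$plant_n, r$cum_fixed_n + r$cum_uptake_n, tolerance = 1e-9)
})

test_that("flood days put the water table at the surface", {
  cfg <- det_config(treatments = list(flood_treatment("V4",
                                                      duration_days = 5)))
  tr <- run_season(cfg)$trace
  expect_equal(sum(tr$flood_forced), 5)
  expect_true(all(tr$water_table[tr$flood_forced] == 0))
  expect_true(all(tr$frac_submerged[tr$flood_forced] == 1))
})

test_that("stage-triggered floods start when the stage is crossed", {
  cfg <- det_config(treatments = list(flood_treatment("R2",
                                                      duration_days = 3)))
  tr <- run_season(cfg)$trace
  first <- which(tr$flood_forced)[1]
  # the trigger fires on the morning after the stage is crossed
  expect_gte(tr$stage[first - 1], 3.5)
  expect_lt(tr$stage[first - 2], 3.5)
  bad <- det_config(treatments = list(flood_treatment("V40",
                                                      duration_days = 2)))
  expect_error(run_season(bad), "V40")
})

test_that("the flood factorial pairs every treatment with its control", {
  fe <- run_flood_experiment(det_config(), c("V4", "R2"), c(2, 7))
  expect_s3_class(fe, "flood_experiment")
  expect_equal(nrow(fe), 5)
  expect_equal(fe$stage[1], "control")
  expect_equal(fe$penalty_pct[1], 0)
  expect_equal(fe$penalty_pct,
               100 * (fe$yield[1] - fe$yield) / fe$yield[1])
  z <- run_flood_experiment(det_config(), c("V4", "R2"), 0)
  expect_true(all(z$yield == z$yield[1]))
  expect_error(run_flood_experiment(det_config(), character(), 2),
               "non-empty")
})

test_that("multi-year runs reset soil state each season", {
  cfg <- fixture_config("clay", n_years = 3, seed = 11)
  res <- run_multi_year(cfg)
  expect_length(res, 3)
  fx <- clay_fixture()
  for (r in res) {
    # sowing-day profile water equals the configured (dul) initial state
    expect_equal(r$trace$sw_mean[1] >= mean(fx$profile$dul) - 0.02, TRUE)
    expect_false(r$truncated)
  }
  yields <- vapply(res, `[[`, 0, "yield")
  expect_gt(var(yields), 0)  # stochastic weather varies year to year
  expect_error(run_multi_year(cfg, 1990, 1995), "cover")
})

test_that("oxdef on/off are identical on a never-waterlogged season", {
  fx <- silt_loam_fixture()
  ws <- det_weather(rain_every = 3, rain_mm = 9)
  on <- sim_config(ws, fx$profile, fx$cultivar, sowing_doy = "05-10",
                   init_mineral_n = 100, mineralization_rate = 0.9,
                   oxdef = oxdef_params(enabled = TRUE))
  off <- on
  off$oxdef <- oxdef_params(enabled = FALSE)
  ron <- run_season(on)
  roff <- run_season(off)
  expect_true(all(ron$trace$wfps_excess == 0))
  expect_true(all(ron$trace$frac_submerged == 0))
  expect_identical(ron$yield, roff$yield)
  expect_identical(ron$trace$biomass, roff$trace$biomass)
})

test_that("improved and original models diverge only under waterlogging", {
  cfg <- det_config(treatments = list(flood_treatment("R2",
                                                      duration_days = 7)))
  off <- cfg
  off$oxdef <- oxdef_params(enabled = FALSE)
  yon <- run_season(cfg)$yield
  yoff <- run_season(off)$yield
  expect_lt(yon, yoff)  # the new functions deepen flood damage
})

test_that("sensitivity runs report all perturbations and pin the fix anchor", {
  cfg <- fixture_config("clay", n_years = 1, seed = 3)
  st <- run_sensitivity(cfg, sd_table = list(photo = 0, pheno = 0, fix = 0),
                        stages = "R2", durations = 7)
  expect_equal(nrow(st), 12)
  num <- c("d_yield_pct", "d_biomass_pct", "d_fixed_n_pct",
           "d_uptake_n_pct", "d_root_depth_pct")
  expect_true(all(abs(unlist(st[num])) < 1e-9))
  expect_true(all(st$pinned_anchor[st$fn == "fix"]))
  expect_false(any(st$pinned_anchor[st$fn != "fix"]))
})

test_that("yield responds more to photosynthesis than phenology parameters", {
  cfg <- fixture_config("silt_loam", n_years = 2, seed = 5)
  st <- run_sensitivity(cfg, stages = c("V4", "R2"), durations = c(2, 7, 14))
  dphoto <- max(abs(st$d_yield_pct[st$fn == "photo"]))
  dpheno <- max(abs(st$d_yield_pct[st$fn == "pheno"]))
  expect_gt(dphoto, dpheno)
  expect_lt(dphoto, 15)  # low single digits to modest, not runaway
})

test_that("risk analysis pairs controls and a null scenario is free", {
  cfg <- fixture_config("clay", n_years = 2, seed = 9)
  rs <- run_risk_analysis(cfg, list(climate_scenario("none")))
  expect_s3_class(rs, "risk_summary")
  expect_equal(rs$mean_penalty_pct, 0)
  yearly <- attr(rs, "yearly")
  expect_equal(nrow(yearly), 2)
  expect_true(all(yearly$penalty_pct == 0))
})
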