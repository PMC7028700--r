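test_that("x/y multipliers interpolate, clamp, and validate", {
  fn <- piecewise_multiplier(c(0, 0.8, 1), c(1, 1, 0.75))
  expect_equal(evaluate_multiplier(fn, 0), 1)
  expect_equal(evaluate_multiplier(fn, 0.9), 0.875)
  expect_equal(evaluate_multiplier(fn, 1.3), 0.75)
  expect_error(piecewise_multiplier(c(0, 0), c(1, 1)), "increasing")
  expect_error(piecewise_multiplier(c(0, 1), c(1, 1.2)), "0, 1")
})

test_that("drought stress is the clamped supply/demand ratio", {
  expect_equal(drought_photo_stress(5, 4), 1)
  expect_equal(drought_photo_stress(2, 4), 0.5)
  expect_equal(drought_photo_stress(3, 0), 1)
  expect_error(drought_photo_stress(-1, 2), "non-negative")
})

test_that("stage severity scales the stress depth", {
  st <- stage_severity(3, 1, 2)
  expect_equal(apply_stage_severity(1, 5, st), 1)
  expect_equal(apply_stage_severity(0.75, 2, st), 0.75)   # S = 1 vegetative
  expect_equal(apply_stage_severity(0.75, 4.5, st), 0.50) # S = 2 reproductive
  expect_error(stage_severity(3, 1, 0.5), "severity")
})

test_that("photosynthesis stress honours the 80% onset and stage factor", {
  ox <- oxdef_params()
  expect_equal(oxdef_photo(c(0, 0.5, 0.8), 2, ox), c(1, 1, 1))
  expect_equal(oxdef_photo(1, 2, ox), 0.75)
  expect_equal(oxdef_photo(1, 4.5, ox), 0.70)  # severity 1.2 at pod fill
})

test_that("phenology stress stalls vegetative plants but relieves at pod fill", {
  ox <- oxdef_params()
  expect_equal(oxdef_pheno(0, 2, ox), 1)
  expect_equal(oxdef_pheno(1, 2, ox), 0.4)
  expect_equal(oxdef_pheno(0.9, 2, ox), 0.7)
  # reproductive crops keep developing: stall depth shrinks by the relief
  expect_equal(oxdef_pheno(1, 4, ox), 1 - 0.6 * ox$pheno_rep_relief)
})

test_that("fixation stress starts at 0.5 and is pinned to 0 at saturation", {
  ox <- oxdef_params()
  expect_equal(oxdef_fix(c(0, 0.25, 0.5), 2, ox), c(1, 1, 1))
  expect_equal(oxdef_fix(0.75, 2, ox), 0.5)
  for (stage in c(1, 2, 3.5, 4.5, 5.5))
    expect_equal(oxdef_fix(1, stage, ox), 0)
  expect_error(oxdef_params(fix = piecewise_multiplier(c(0, 1), c(1, 0.1))),
               "y = 0")
})

test_that("post-flood recovery is full before R1 and capped after", {
  ox <- oxdef_params(recovery_persistence = 0.5)
  carry <- new_carry_state()
  # vegetative flood: stress passes through, then full recovery
  r <- post_flood_recovery(0.6, TRUE, 2, ox, carry)
  expect_equal(r$mult, 0.6)
  r2 <- post_flood_recovery(1, FALSE, 2.5, ox, r$carry)
  expect_equal(r2$mult, 1)
  # reproductive flood that bottomed at 0.60 caps later stress at 0.80
  carry_rep <- list(min_mult = 0.60, max_stage = 3.5)
  expect_equal(post_flood_recovery(1, FALSE, 4, ox, carry_rep)$mult, 0.80)
  ox0 <- oxdef_params(recovery_persistence = 0)
  expect_equal(post_flood_recovery(1, FALSE, 4, ox0, carry_rep)$mult, 1)
})

test_that("sensitivity perturbations shift y values but pin the fix anchor", {
  ox <- oxdef_params()
  up <- perturb_params(ox, "photo", 2, list(photo = 0.05, pheno = 0.05,
                                            fix = 0.05))
  expect_equal(up$photo$ys, c(1, 1, 0.85))
  for (nsd in c(-2, -1, 1, 2))
    expect_equal(tail(perturb_params(ox, "fix", nsd)$fix$ys, 1), 0)
  none <- perturb_params(ox, "pheno", 1, list(photo = 0, pheno = 0, fix = 0))
  expect_equal(none$pheno$ys, ox$pheno$ys)
})

test_that("all stress functions stay in [0,1] and fall with their predictor", {
  set.seed(99)
  for (rep in 1:25) {
    ox <- oxdef_params(
      photo = piecewise_multiplier(c(0, 0.8, 1), c(1, 1, runif(1, 0.5, 1))),
      pheno = piecewise_multiplier(c(0, 0.8, 1), c(1, 1, runif(1, 0.2, 1))),
      fix = piecewise_multiplier(c(0, 0.5, 1), c(1, runif(1, 0.5, 1), 0)),
      stage = stage_severity(3, 1, runif(1, 1, 2)))
    stage <- runif(1, 0, 6)
    x <- sort(runif(6))
    for (f in list(oxdef_photo, oxdef_pheno, oxdef_fix)) {
      y <- f(x, stage, ox)
      expect_true(all(y >= 0 & y <= 1))
      expect_true(all(diff(y) <= 1e-12))
    }
  }
})

test_that("photosynthesis and fixation stress deepen with reproductive stage", {
  ox <- oxdef_params()
  x <- seq(0, 1, by = 0.1)
  expect_true(all(oxdef_photo(x, 4.5, ox) <= oxdef_photo(x, 2, ox)))
  expect_true(all(oxdef_fix(x, 4.5, ox) <= oxdef_fix(x, 2, ox)))
})

test_that("disabling the waterlogging functions reduces them to unity", {
  ox <- oxdef_params(enabled = FALSE)
  x <- c(0, 0.5, 0.9, 1)
  expect_equal(oxdef_photo(x, 4, ox), rep(1, 4))
  expect_equal(oxdef_pheno(x, 4, ox), rep(1, 4))
  expect_equal(oxdef_fix(x, 4, ox), rep(1, 4))
})
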