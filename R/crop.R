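# Continuous stage-code anchors: 0 sowing, 1 emergence, 3 R1 (flowering),
# 4 R3 (pod-fill start), 5 R5 (pod-fill end), 6 maturity. V-stage numbers
# are tracked separately within the vegetative phase (emergence -> R1).
STAGE_SOWING    <- 0
STAGE_EMERGENCE <- 1
STAGE_R1        <- 3
STAGE_R3        <- 4
STAGE_R5        <- 5
STAGE_MATURITY  <- 6

#' Cultivar parameter set
#'
#' Thermal-time phase targets, growth coefficients and N economy parameters
#' for a soybean cultivar. Maturity group (MG) spans 3-5.5; higher groups
#' have longer thermal-time targets.
#'
#' @param maturity_group dimensionless MG in [3, 5.5].
#' @param tt_targets named numeric, degree-days per phase:
#'   `sow_emerge`, `emerge_r1`, `r1_r3`, `r3_r5`, `r5_mat`.
#' @param base_temp,opt_temp cardinal temperatures (degrees C) for thermal
#'   time.
#' @param rue radiation-use efficiency (g biomass MJ-1 intercepted).
#' @param te_coeff transpiration-efficiency coefficient
#'   (kPa g m-2 mm-1 scale; demand = growth x VPD / te / 1000).
#' @param k_extinction canopy light extinction coefficient.
#' @param max_root_depth,root_elong_rate rooting limit (mm) and daily
#'   elongation rate (mm d-1).
#' @param max_lai canopy leaf-area-index ceiling (m2 m-2).
#' @param phyllochron degree-days per vegetative node (V stage).
#' @param grain_fill_fraction fraction of daily growth routed to grain
#'   between R3 and maturity.
#' @param n_conc_veg,n_conc_grain N concentration of new vegetative and grain
#'   biomass (g N g-1).
#' @param potential_fix_rate peak symbiotic fixation rate (kg N ha-1 d-1).
#' @param max_n_uptake_rate cap on daily soil mineral-N uptake
#'   (kg N ha-1 d-1).
#' @param pod_set_coeff kg of grain sink capacity set per kg of growth
#'   during the R1-R5 pod-set window.
#' @param abort_rate daily fraction of pod capacity aborted while tissue N
#'   sufficiency is below `abort_threshold` during the pod-set window.
#' @param abort_threshold N-sufficiency level below which pods abort.
#' @return An object of class `cultivar`.
#' @export
cultivar <- function(maturity_group = 4,
                     tt_targets = c(sow_emerge = 125, emerge_r1 = 880,
                                    r1_r3 = 440, r3_r5 = 505, r5_mat = 505),
                     base_temp = 6, opt_temp = 30,
                     rue = 0.80, te_coeff = 0.006, k_extinction = 0.55,
                     max_root_depth = 1500, root_elong_rate = 30,
                     max_lai = 4.2, phyllochron = 70,
                     grain_fill_fraction = 0.66,
                     n_conc_veg = 0.025, n_conc_grain = 0.040,
                     potential_fix_rate = 6, max_n_uptake_rate = 6,
                     pod_set_coeff = 0.73, abort_rate = 0.35,
                     abort_threshold = 0.55) {
  if (maturity_group < 3 || maturity_group > 5.5)
    stop("maturity_group must lie in [3, 5.5]")
  if (base_temp >= opt_temp) stop("base_temp must be below opt_temp")
  need <- c("sow_emerge", "emerge_r1", "r1_r3", "r3_r5", "r5_mat")
  if (!all(need %in% names(tt_targets)))
    stop("tt_targets needs phases: ", paste(need, collapse = ", "))
  vals <- c(maturity_group, unlist(tt_targets), rue, te_coeff, k_extinction,
            max_root_depth, root_elong_rate, max_lai, phyllochron,
            grain_fill_fraction, n_conc_veg, n_conc_grain,
            potential_fix_rate, max_n_uptake_rate, pod_set_coeff)
  if (any(vals <= 0)) stop("all cultivar parameters must be positive")
  structure(list(maturity_group = maturity_group,
                 tt_targets = tt_targets[need], base_temp = base_temp,
                 opt_temp = opt_temp, rue = rue, te_coeff = te_coeff,
                 k_extinction = k_extinction, max_root_depth = max_root_depth,
                 root_elong_rate = root_elong_rate, max_lai = max_lai,
                 phyllochron = phyllochron,
                 grain_fill_fraction = grain_fill_fraction,
                 n_conc_veg = n_conc_veg, n_conc_grain = n_conc_grain,
                 potential_fix_rate = potential_fix_rate,
                 max_n_uptake_rate = max_n_uptake_rate,
                 pod_set_coeff = pod_set_coeff, abort_rate = abort_rate,
                 abort_threshold = abort_threshold),
            class = "cultivar")
}

#' Maturity-group cultivar presets
#'
#' Named presets for MG 3, 4, 5 and 5.5; thermal-time targets scale with
#' maturity group so higher groups mature later under the same weather.
#'
#' @param mg one of 3, 4, 5, 5.5.
#' @return A [cultivar()].
#' @export
cultivar_preset <- function(mg = 4) {
  scale <- c("3" = 0.78, "4" = 1, "5" = 1.1, "5.5" = 1.16)[as.character(mg)]
  if (is.na(scale)) stop("no preset for maturity group ", mg)
  base <- c(sow_emerge = 125, emerge_r1 = 880, r1_r3 = 440,
            r3_r5 = 505, r5_mat = 505)
  tt <- base
  tt[-1] <- round(base[-1] * scale)
  cultivar(maturity_group = mg, tt_targets = tt)
}

#' Crop state
#'
#' Pools and stage advanced by the daily loop. `stage_code` is continuous on
#' the 0-6 anchor scale; `v_stage` counts vegetative nodes.
#'
#' @param lai_init initial leaf area index assigned at emergence.
#' @param root_depth_init initial rooting depth at sowing (mm).
#' @return An object of class `crop_state`.
#' @export
crop_state <- function(lai_init = 0.1, root_depth_init = 50) {
  structure(list(stage_code = 0, v_stage = 0, cum_tt = 0,
                 biomass = 20, lai = 0, lai_init = lai_init,
                 root_depth = root_depth_init, grain = 0, pod_capacity = 0,
                 pod_abort = 1,
                 plant_n = 20 * 0.04, cum_fixed_n = 0, cum_uptake_n = 20 * 0.04,
                 n_sufficiency = 1,
                 photo_carry = new_carry_state(),
                 fix_carry = new_carry_state()),
            class = "crop_state")
}

#' Daily thermal time
#'
#' @param tmax,tmin daily extremes (degrees C), `tmax >= tmin`.
#' @param base_temp,opt_temp cardinal temperatures (degrees C).
#' @return `max(0, min(mean_temp, opt_temp) - base_temp)` in degree-days.
#' @export
daily_thermal_time <- function(tmax, tmin, base_temp, opt_temp) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  pmax(0, pmin((tmax + tmin) / 2, opt_temp) - base_temp)
}

# cumulative thermal time at each stage anchor; emergence -> R1 spans two
# code units (1 -> 3), the other phases one each
stage_tt_breaks <- function(cv) {
  tt <- cv$tt_targets
  cum <- cumsum(c(0, tt))
  list(codes = c(STAGE_SOWING, STAGE_EMERGENCE, STAGE_R1, STAGE_R3,
                 STAGE_R5, STAGE_MATURITY),
       cum_tt = unname(cum))
}

stage_from_tt <- function(cum_tt, cv) {
  br <- stage_tt_breaks(cv)
  if (cum_tt >= tail1(br$cum_tt)) return(STAGE_MATURITY)
  i <- findInterval(cum_tt, br$cum_tt)
  lo <- br$cum_tt[i]; hi <- br$cum_tt[i + 1L]
  br$codes[i] + (cum_tt - lo) / (hi - lo) * (br$codes[i + 1L] - br$codes[i])
}

#' Advance phenology by one day
#'
#' Thermal time accumulates at `tt_today * pheno_multiplier`; a multiplier of
#' 0 stalls development entirely. The V-stage counter advances one node per
#' phyllochron during the vegetative phase.
#'
#' @param state a [crop_state()].
#' @param tt_today today's thermal time (degree-days).
#' @param pheno_multiplier development-rate multiplier in [0, 1].
#' @param cv a [cultivar()].
#' @return The updated `crop_state`.
#' @export
advance_phenology <- function(state, tt_today, pheno_multiplier, cv) {
  if (pheno_multiplier < 0 || pheno_multiplier > 1)
    stop("pheno_multiplier must lie in [0, 1]")
  state$cum_tt <- state$cum_tt + tt_today * pheno_multiplier
  new_code <- stage_from_tt(state$cum_tt, cv)
  if (state$stage_code < STAGE_EMERGENCE && new_code >= STAGE_EMERGENCE)
    state$lai <- state$lai_init
  state$stage_code <- max(state$stage_code, new_code)
  tt_veg <- state$cum_tt - cv$tt_targets[["sow_emerge"]]
  if (state$stage_code >= STAGE_EMERGENCE)
    state$v_stage <- max(state$v_stage, floor(tt_veg / cv$phyllochron))
  state
}

#' Beer's-law intercepted radiation
#'
#' @param radn incident radiation (MJ m-2).
#' @param lai leaf area index.
#' @param k_extinction extinction coefficient.
#' @return Intercepted radiation, `radn * (1 - exp(-k * lai))` (MJ m-2).
#' @export
intercepted_radiation <- function(radn, lai, k_extinction) {
  if (any(lai < 0)) stop("lai must be non-negative")
  radn * (1 - exp(-k_extinction * lai))
}

#' Daily biomass growth
#'
#' Radiation-limited growth reduced by the binding one of the water and N
#' multipliers (stresses combine by `min`, the convention of the framework).
#'
#' @param intercepted intercepted radiation (MJ m-2).
#' @param rue radiation-use efficiency (g MJ-1).
#' @param water_photo_multiplier combined drought/waterlogging multiplier
#'   in [0, 1] (the binding of the two).
#' @param n_stress_multiplier N-sufficiency multiplier in [0, 1].
#' @return Biomass increment in kg ha-1 (1 g m-2 = 10 kg ha-1).
#' @export
daily_growth <- function(intercepted, rue, water_photo_multiplier,
                         n_stress_multiplier) {
  m <- c(water_photo_multiplier, n_stress_multiplier)
  if (any(m < 0 | m > 1)) stop("multipliers must lie in [0, 1]")
  intercepted * rue * min(water_photo_multiplier, n_stress_multiplier) * 10
}

# daytime VPD from the daily extremes (0.75-weighted SVP difference)
daytime_vpd <- function(tmax, tmin) {
  svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  pmax(0.05, 0.75 * (svp(tmax) - svp(tmin)))
}

#' Transpiration demand from potential growth
#'
#' Potential growth is converted to water demand through a transpiration
#' efficiency coefficient normalised for vapour pressure deficit.
#'
#' @param potential_growth_g_m2 potential growth (g m-2 d-1).
#' @param te_coeff transpiration efficiency coefficient.
#' @param vpd_kpa daytime vapour pressure deficit (kPa, > 0).
#' @return Demand in mm d-1.
#' @export
transpiration_demand <- function(potential_growth_g_m2, te_coeff, vpd_kpa) {
  if (any(vpd_kpa <= 0)) stop("vpd must be positive")
  potential_growth_g_m2 * vpd_kpa / te_coeff / 1000
}

#' Daily root elongation
#'
#' Roots elongate at `root_elong_rate` unless the air-filled porosity at the
#' root front is below 3 percent (hypoxic arrest); depth never shrinks and
#' never exceeds `max_root_depth`.
#'
#' @param state a [crop_state()].
#' @param profile a [soil_profile()].
#' @param soil_state a [soil_water_state()].
#' @param cv a [cultivar()].
#' @return The new rooting depth (mm).
#' @export
root_growth <- function(state, profile, soil_state, cv) {
  d <- state$root_depth
  front <- min(d, profile$depth - 1e-9)
  afp <- air_filled_porosity_at(profile, soil_state, front)
  if (afp >= 0.03 && state$stage_code >= STAGE_EMERGENCE &&
      state$stage_code < STAGE_R5)
    d <- d + cv$root_elong_rate
  min(d, cv$max_root_depth)
}

# stage-dependent fixation capacity: ramps 0 -> 1 from emergence to R3,
# holds 1 through R5 (fixation peaks during pod fill), then tapers
stage_fix_curve <- function(stage_code) {
  ramp_up <- pmin(1, pmax(0, (stage_code - STAGE_EMERGENCE) /
                               (STAGE_R3 - STAGE_EMERGENCE)))
  taper <- pmin(1, pmax(0.3, 1 - 0.7 * (stage_code - STAGE_R5)))
  ifelse(stage_code <= STAGE_R5, ramp_up, taper)
}

#' Daily N uptake and symbiotic fixation
#'
#' Soil mineral N is taken up first (from non-saturated root-zone layers,
#' capped by the daily uptake rate); symbiotic fixation then covers the
#' remaining demand up to the stage-dependent fixation capacity scaled by the
#' waterlogging fixation multiplier.
#'
#' @param demand_kg today's plant N demand (kg N ha-1).
#' @param accessible_soil_n mineral N accessible in non-saturated root-zone
#'   layers (kg N ha-1).
#' @param fix_multiplier waterlogging fixation multiplier in [0, 1].
#' @param stage_code continuous stage code.
#' @param cv a [cultivar()].
#' @return List with `uptake`, `fixed` (kg N ha-1) and `n_stress_multiplier`
#'   = (uptake + fixed)/demand clamped to [0, 1] (1 when demand is 0).
#' @export
n_uptake_and_fixation <- function(demand_kg, accessible_soil_n,
                                  fix_multiplier, stage_code, cv) {
  if (any(c(demand_kg, accessible_soil_n, fix_multiplier) < 0))
    stop("N inputs must be non-negative")
  uptake <- min(demand_kg, accessible_soil_n, cv$max_n_uptake_rate)
  pot_fix <- cv$potential_fix_rate * stage_fix_curve(stage_code) *
    fix_multiplier
  fixed <- min(max(0, demand_kg - uptake), pot_fix)
  stress <- if (demand_kg == 0) 1 else
    min(1, max(0, (uptake + fixed) / demand_kg))
  list(uptake = uptake, fixed = fixed, n_stress_multiplier = stress)
}

#' Daily grain fill
#'
#' Between R3 and maturity a fixed fraction of the day's biomass increment is
#' routed to grain; after R5 a small retranslocation term (0.2 percent of
#' vegetative biomass per day) tops it up. The grain pool can never exceed
#' the pod sink capacity set during the R1-R5 window (see
#' [update_pod_capacity()]). Yield at maturity is the grain pool.
#'
#' @param state a [crop_state()].
#' @param daily_biomass_increment today's growth (kg ha-1).
#' @param cv a [cultivar()].
#' @return The updated `crop_state`.
#' @export
grain_fill <- function(state, daily_biomass_increment, cv) {
  if (state$stage_code < STAGE_R3 || state$stage_code >= STAGE_MATURITY)
    return(state)
  inc <- cv$grain_fill_fraction * daily_biomass_increment
  if (state$stage_code >= STAGE_R5) {
    veg <- max(0, state$biomass - state$grain)
    inc <- inc + 0.002 * veg
  }
  inc <- min(inc, max(0, state$pod_capacity - state$grain))
  state$grain <- min(state$biomass, state$grain + inc)
  state
}

#' Pod sink capacity: set and abortion
#'
#' Grain sink capacity accrues in proportion to crop growth during the
#' flowering-to-R5 window (`pod_set_coeff` kg capacity per kg growth); while
#' tissue N sufficiency is below `abort_threshold` inside that window,
#' existing capacity and the pod-set potential itself are aborted at
#' `abort_rate` per day. This is what makes reproductive-stage floods
#' durably damaging in proportion to their length: the assimilate and N
#' missed while flooded set fewer pods, and sustained starvation aborts
#' pods and flower sites already formed.
#'
#' @param state a [crop_state()].
#' @param daily_biomass_increment today's growth (kg ha-1).
#' @param n_sufficiency lagged tissue N-sufficiency index in [0, 1].
#' @param cv a [cultivar()].
#' @return The updated `crop_state`.
#' @export
update_pod_capacity <- function(state, daily_biomass_increment,
                                n_sufficiency, cv) {
  if (state$stage_code < STAGE_R1 || state$stage_code >= STAGE_R5)
    return(state)
  if (n_sufficiency < cv$abort_threshold) {
    # starvation destroys set pods and flower/raceme sites alike, so the
    # loss also depresses all subsequent pod set; intensity grows smoothly
    # with the depth of starvation below the threshold
    rate <- cv$abort_rate * (cv$abort_threshold - n_sufficiency) /
      cv$abort_threshold
    state$pod_abort <- state$pod_abort * (1 - rate)
    state$pod_capacity <- state$pod_capacity * (1 - rate)
  }
  state$pod_capacity <- state$pod_capacity +
    cv$pod_set_coeff * state$pod_abort * daily_biomass_increment
  state
}
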