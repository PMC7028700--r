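# smoothing constant of the plant N-sufficiency index (d-1); tissue N status
# responds to supply with a lag of roughly a week
N_SUFFICIENCY_ALPHA <- 0.15

#' Flood treatment
#'
#' A flood window triggered either by the crop reaching a stage (`"V4"`,
#' `"R2"`, or a numeric stage code) or by a calendar day of year. During the
#' window the profile is forced to saturation each day (water table at the
#' surface), emulating rain added until the table reaches the surface.
#'
#' @param trigger_stage stage label (`"V1"`..., `"R1"`, `"R2"`, `"R3"`,
#'   `"R5"`) or numeric stage code; `NULL` for calendar triggering.
#' @param trigger_doy day of year starting the window (calendar trigger).
#' @param duration_days length of the window (>= 0; 0 is a no-op control).
#' @return An object of class `flood_treatment`.
#' @export
flood_treatment <- function(trigger_stage = NULL, trigger_doy = NULL,
                            duration_days = 0) {
  if (duration_days < 0) stop("duration_days must be >= 0")
  if (is.null(trigger_stage) && is.null(trigger_doy) && duration_days > 0)
    stop("a flood treatment needs a stage or calendar trigger")
  structure(list(trigger_stage = trigger_stage, trigger_doy = trigger_doy,
                 duration_days = as.integer(duration_days)),
            class = "flood_treatment")
}

# resolve a stage trigger to a test on today's crop state
trigger_met <- function(tr, crop) {
  ts <- tr$trigger_stage
  if (is.null(ts)) return(FALSE)
  if (is.character(ts)) {
    if (grepl("^V[0-9]+$", ts))
      return(crop$stage_code >= STAGE_EMERGENCE &&
               crop$v_stage >= as.integer(sub("V", "", ts)))
    code <- c(R1 = 3, R2 = 3.5, R3 = 4, R4 = 4.5, R5 = 5)[ts]
    if (is.na(code)) stop("unknown stage label: ", ts)
    return(crop$stage_code >= code)
  }
  crop$stage_code >= as.numeric(ts)
}

#' Simulation configuration
#'
#' @param weather a [weather_series()] (scenarios are applied to it before
#'   the daily loop).
#' @param profile a [soil_profile()].
#' @param cv a [cultivar()].
#' @param sowing_doy sowing day of year (integer) or `"mm-dd"` string.
#' @param oxdef an [oxdef_params()]; set `enabled = FALSE` for the original
#'   (pre-improvement) model.
#' @param treatments list of [flood_treatment()] objects (empty = control).
#' @param scenario optional [climate_scenario()].
#' @param init_sw initial volumetric water per layer at sowing (default
#'   `dul`, the annual-reset convention).
#' @param init_mineral_n initial profile mineral N at sowing (kg N ha-1),
#'   distributed over the top 600 mm.
#' @param mineralization_rate fixed daily mineral-N input (kg N ha-1 d-1),
#'   unaffected by waterlogging.
#' @param seed integer seed recorded in all outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(weather, profile, cv, sowing_doy = "05-15",
                       oxdef = oxdef_params(), treatments = list(),
                       scenario = NULL, init_sw = NULL, init_mineral_n = 60,
                       mineralization_rate = 0.8, seed = 1L) {
  if (inherits(treatments, "flood_treatment")) treatments <- list(treatments)
  if (is.character(sowing_doy))
    sowing_doy <- as.integer(format(as.Date(paste0("2001-", sowing_doy)),
                                    "%j"))
  structure(list(weather = validate_weather(weather), profile = profile,
                 cv = cv, sowing_doy = as.integer(sowing_doy), oxdef = oxdef,
                 treatments = treatments, scenario = scenario,
                 init_sw = init_sw, init_mineral_n = init_mineral_n,
                 mineralization_rate = mineralization_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

init_mineral_n_by_layer <- function(profile, total) {
  tin <- pmax(0, pmin(profile$depth_bottom, 600) - profile$depth_top)
  if (sum(tin) == 0) tin <- profile$thickness
  total * tin / sum(tin)
}

accessible_soil_n <- function(profile, state, root_depth) {
  tin <- pmax(0, pmin(profile$depth_bottom, root_depth) - profile$depth_top)
  frac <- tin / profile$thickness
  satd <- state$sw >= profile$sat - SAT_EPS
  sum(ifelse(satd, 0, state$mineral_n * frac))
}

take_soil_n <- function(profile, state, root_depth, amount) {
  if (amount <= 0) return(state)
  tin <- pmax(0, pmin(profile$depth_bottom, root_depth) - profile$depth_top)
  frac <- tin / profile$thickness
  satd <- state$sw >= profile$sat - SAT_EPS
  acc <- ifelse(satd, 0, state$mineral_n * frac)
  tot <- sum(acc)
  if (tot <= 0) return(state)
  state$mineral_n <- state$mineral_n - amount * acc / tot
  state$mineral_n[state$mineral_n < 0] <- 0
  state
}

# Extract transpiration: unsaturated root-zone layers first (kl-weighted),
# then the top of the saturated zone (submerged roots sit in free water and
# their uptake recedes the table from above).
extract_transpiration <- function(profile, state, root_depth, total) {
  n <- length(profile$thickness)
  tr <- numeric(n)
  if (total <= 0) return(list(state = state, by_layer = tr))
  th <- profile$thickness
  tin <- pmax(0, pmin(profile$depth_bottom, root_depth) - profile$depth_top)
  satd <- state$sw >= profile$sat - SAT_EPS
  avail <- ifelse(satd, 0, tin * pmax(0, state$sw - profile$ll15) * profile$kl)
  left <- total
  if (sum(avail) > 0) {
    t1 <- pmin(avail, avail / sum(avail) * min(left, sum(avail)))
    tr <- tr + t1
    left <- left - sum(t1)
  }
  if (left > 1e-12) {
    for (i in which(satd & tin > 0)) {   # top-down within the table
      cap <- max(0, (state$sw[i] - profile$ll15[i]) * th[i] - tr[i])
      take <- min(left, cap)
      tr[i] <- tr[i] + take
      left <- left - take
      if (left <= 1e-12) break
    }
  }
  state$sw <- state$sw - tr / th
  state$cum_transp <- state$cum_transp + sum(tr)
  list(state = state, by_layer = tr)
}

#' Run one cropping season
#'
#' The daily loop, in fixed order: weather (scenario pre-applied) -> flood
#' forcing if a treatment window is active -> soil water balance ->
#' water-table and stress-predictor diagnostics -> phenology (waterlogging
#' multiplier applied to thermal time) -> root growth -> water supply/demand
#' and drought stress -> waterlogging photosynthesis stress with post-flood
#' recovery -> N uptake and fixation (waterlogging fixation stress) ->
#' biomass growth and transpiration -> grain fill -> trace append. The
#' season ends at maturity or when the weather runs out (with a warning and
#' a `truncated` flag).
#'
#' @param config a [sim_config()].
#' @return An object of class `season_result`: yield and final biomass
#'   (kg ha-1), cumulative fixed and taken-up N (kg N ha-1), maturity date,
#'   maximum root depth, a per-day `trace` data frame, and a water-balance
#'   ledger.
#' @export
run_season <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ws <- config$weather
  if (!is.null(config$scenario)) ws <- apply_scenario(ws, config$scenario)
  profile <- config$profile
  cv <- config$cv
  ox <- config$oxdef

  doy <- as.integer(format(ws$date, "%j"))
  start <- which(doy == config$sowing_doy)[1L]
  if (is.na(start)) stop("sowing day of year ", config$sowing_doy,
                         " not found in the weather series")

  soil <- soil_water_state(profile, sw = config$init_sw,
                           mineral_n = init_mineral_n_by_layer(
                             profile, config$init_mineral_n))
  crop <- crop_state()
  n_target <- crop$plant_n
  storage0 <- stored_water(profile, soil)

  # resolve treatment windows (calendar triggers now, stage triggers lazily)
  windows <- lapply(config$treatments, function(tr) {
    if (tr$duration_days == 0) return(NULL)
    if (!is.null(tr$trigger_doy)) {
      s <- which(doy == tr$trigger_doy & seq_along(doy) >= start)[1L]
      if (is.na(s)) stop("treatment day of year ", tr$trigger_doy,
                         " not reached in the season")
      s <- s - start + 1L   # season-relative day index
      return(list(start = s, end = s + tr$duration_days - 1L, tr = tr))
    }
    list(start = NA_integer_, end = NA_integer_, tr = tr)  # stage-triggered
  })
  windows <- Filter(Negate(is.null), windows)

  nmax <- nrow(ws) - start + 1L
  trace <- vector("list", nmax)
  truncated <- TRUE
  maturity_date <- as.Date(NA)

  for (t in seq_len(nmax)) {
    i <- start + t - 1L
    rain <- ws$rain[i]

    # stage triggers fire on the first day the stage is crossed
    for (k in seq_along(windows)) {
      w <- windows[[k]]
      if (is.na(w$start) && trigger_met(w$tr, crop)) {
        windows[[k]]$start <- t
        windows[[k]]$end <- t + w$tr$duration_days - 1L
      }
    }
    flood_forced <- any(vapply(windows, function(w)
      !is.na(w$start) && t >= w$start && t <= w$end, logical(1)))

    evap_demand <- 1.3 * exp(-0.4 * crop$lai)
    if (flood_forced) {
      # ponded water keeps the profile saturated; evapotranspiration is
      # resupplied by the flood and logged as flood-water input
      soil <- step_water_balance(profile, soil, rain, 0, 0)
      soil <- force_flood(profile, soil)
    } else {
      soil <- step_water_balance(profile, soil, rain, evap_demand, 0)
    }
    soil$mineral_n[1L] <- soil$mineral_n[1L] + config$mineralization_rate

    wt <- water_table_depth(profile, soil)
    fsub <- fraction_roots_submerged(crop$root_depth, wt)
    wfps <- wfps_excess_fraction(profile, soil, ox$fix_activation_depth)

    # phenology
    tt <- daily_thermal_time(ws$tmax[i], ws$tmin[i], cv$base_temp, cv$opt_temp)
    pheno_m <- oxdef_pheno(fsub, crop$stage_code, ox)
    crop <- advance_phenology(crop, tt, pheno_m, cv)

    crop$root_depth <- min(root_growth(crop, profile, soil, cv),
                           profile$depth)

    # potential growth, water demand/supply, drought stress
    icpt <- intercepted_radiation(ws$radn[i], crop$lai, cv$k_extinction)
    pot_g_m2 <- icpt * cv$rue
    vpd <- daytime_vpd(ws$tmax[i], ws$tmin[i])
    demand <- transpiration_demand(pot_g_m2, cv$te_coeff, vpd)
    supply <- available_supply(profile, soil, crop$root_depth)
    # submerged roots are in contact with free water: the supply/demand
    # ratio is floored by the submerged fraction (no drought in a flood)
    drought <- if (demand == 0) 1 else
      min(1, (supply + fsub * demand) / demand)

    photo_raw <- oxdef_photo(fsub, crop$stage_code, ox)
    rec <- post_flood_recovery(photo_raw, photo_raw < 1 - 1e-9,
                               crop$stage_code, ox, crop$photo_carry)
    crop$photo_carry <- rec$carry
    photo_eff <- rec$mult
    water_mult <- min(drought, photo_eff)

    # N economy: soil uptake first, then fixation
    fix_raw <- oxdef_fix(wfps, crop$stage_code, ox)
    recf <- post_flood_recovery(fix_raw, fix_raw < 1 - 1e-9,
                                crop$stage_code, ox, crop$fix_carry)
    crop$fix_carry <- recf$carry
    fix_eff <- recf$mult

    growing <- crop$stage_code >= STAGE_EMERGENCE &&
      crop$stage_code < STAGE_MATURITY
    conc <- if (crop$stage_code < STAGE_R3) cv$n_conc_veg else
      cv$grain_fill_fraction * cv$n_conc_grain +
        (1 - cv$grain_fill_fraction) * cv$n_conc_veg
    dw_water <- icpt * cv$rue * water_mult * 10
    deficit <- max(0, n_target - crop$plant_n)
    n_demand <- if (growing) conc * dw_water + 0.2 * deficit else 0
    acc_n <- accessible_soil_n(profile, soil, crop$root_depth)
    nres <- n_uptake_and_fixation(n_demand, acc_n, fix_eff,
                                  crop$stage_code, cv)
    soil <- take_soil_n(profile, soil, crop$root_depth, nres$uptake)
    crop$plant_n <- crop$plant_n + nres$uptake + nres$fixed
    crop$cum_uptake_n <- crop$cum_uptake_n + nres$uptake
    crop$cum_fixed_n <- crop$cum_fixed_n + nres$fixed

    # growth responds concavely to the lagged tissue N status: moderate
    # dilution costs little, severe starvation is crippling
    n_mult <- sqrt(crop$n_sufficiency)
    dw <- if (growing) daily_growth(icpt, cv$rue, water_mult, n_mult) else 0
    crop$n_sufficiency <- (1 - N_SUFFICIENCY_ALPHA) * crop$n_sufficiency +
      N_SUFFICIENCY_ALPHA * nres$n_stress_multiplier
    n_target <- n_target + conc * dw

    crop$biomass <- crop$biomass + dw
    crop <- update_pod_capacity(crop, dw, n_mult, cv)
    crop <- grain_fill(crop, dw, cv)

    # canopy dynamics
    if (growing) {
      leaf_frac <- 0.4 * min(1, max(0, (STAGE_R3 - crop$stage_code) /
                                         (STAGE_R3 - STAGE_R1)))
      crop$lai <- min(cv$max_lai, crop$lai + dw / 10 * leaf_frac * 0.022)
      if (crop$stage_code >= STAGE_R5) crop$lai <- crop$lai * 0.985
    }

    # transpiration follows realized (water-limited) assimilation, further
    # depressed by hypoxic loss of root hydraulic conductance while the
    # water table is inside the root zone
    transp <- demand * water_mult * (1 - 0.5 * fsub)
    if (flood_forced) {
      soil$cum_transp <- soil$cum_transp + transp
      soil$cum_evap <- soil$cum_evap + evap_demand
      soil$cum_flood_water <- soil$cum_flood_water + transp + evap_demand
    } else {
      soil <- extract_transpiration(profile, soil, crop$root_depth,
                                    transp)$state
    }

    trace[[t]] <- data.frame(
      date = ws$date[i], stage = crop$stage_code, v_stage = crop$v_stage,
      biomass = crop$biomass, lai = crop$lai, grain = crop$grain,
      root_depth = crop$root_depth, water_table = wt,
      frac_submerged = fsub, wfps_excess = wfps,
      drought = drought, photo = photo_eff, pheno = pheno_m, fix = fix_eff,
      n_ratio = nres$n_stress_multiplier, n_sufficiency = n_mult,
      pod_capacity = crop$pod_capacity, pod_abort = crop$pod_abort,
      growth = dw, rain = rain, flood_forced = flood_forced,
      sw_mean = mean(soil$sw))

    if (crop$stage_code >= STAGE_MATURITY) {
      truncated <- FALSE
      maturity_date <- ws$date[i]
      break
    }
  }
  for (w in windows)
    if (is.na(w$start))
      stop("flood trigger stage ", w$tr$trigger_stage,
           " was never reached in the season")
  if (truncated) {
    warning("weather series exhausted before maturity; season truncated")
    maturity_date <- ws$date[nrow(ws)]
  }

  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  balance <- list(
    rain = sum(trace$rain), flood_water = soil$cum_flood_water,
    runoff = soil$cum_runoff, drainage = soil$cum_drainage,
    evaporation = soil$cum_evap, transpiration = soil$cum_transp,
    delta_storage = stored_water(profile, soil) - storage0)
  balance$closure <- with(balance, rain + flood_water - runoff - drainage -
                            evaporation - transpiration - delta_storage)

  structure(list(
    yield = crop$grain, biomass = crop$biomass,
    cum_fixed_n = crop$cum_fixed_n, cum_uptake_n = crop$cum_uptake_n,
    plant_n = crop$plant_n, maturity_date = maturity_date,
    max_root_depth = max(trace$root_depth), truncated = truncated,
    trace = trace, water_balance = balance, seed = config$seed,
    oxdef_enabled = config$oxdef$enabled),
    class = "season_result")
}

#' Flood-duration/timing factorial experiment
#'
#' Runs a control season plus every combination of trigger stage and flood
#' duration, sharing weather, soil and cultivar with the control, and pairs
#' each treatment with the control for penalty computation.
#'
#' @param config a [sim_config()] (its `treatments` are replaced).
#' @param stages character/numeric vector of trigger stages (e.g.
#'   `c("V4", "R2")`).
#' @param durations integer flood durations in days.
#' @return A data frame of class `flood_experiment` with one row per run
#'   (control first) and columns `stage`, `duration_days`, `yield`,
#'   `biomass`, `cum_fixed_n`, `cum_uptake_n`, `maturity_date`,
#'   `penalty_pct` (percent yield loss vs control).
#' @export
run_flood_experiment <- function(config, stages, durations) {
  if (!length(stages) || !length(durations))
    stop("stages and durations must be non-empty")
  base <- config
  base$treatments <- list()
  ctrl <- run_season(base)
  rows <- list(data.frame(stage = "control", duration_days = 0L,
                          yield = ctrl$yield, biomass = ctrl$biomass,
                          cum_fixed_n = ctrl$cum_fixed_n,
                          cum_uptake_n = ctrl$cum_uptake_n,
                          maturity_date = ctrl$maturity_date,
                          penalty_pct = 0))
  for (s in stages) for (d in durations) {
    cfg <- config
    cfg$treatments <- list(flood_treatment(trigger_stage = s,
                                           duration_days = d))
    r <- run_season(cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      stage = as.character(s), duration_days = as.integer(d),
      yield = r$yield, biomass = r$biomass, cum_fixed_n = r$cum_fixed_n,
      cum_uptake_n = r$cum_uptake_n, maturity_date = r$maturity_date,
      penalty_pct = yield_penalty_percent(r$yield, ctrl$yield))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("flood_experiment", "data.frame")
  out
}

#' Multi-year run with annual reset
#'
#' Each calendar year is simulated as an independent season: soil water and
#' mineral N are reset to their configured initial values (the January-1
#' reset protocol) and the crop is sown on the configured day of year.
#'
#' @param config a [sim_config()] whose weather spans the year range.
#' @param start_year,end_year inclusive calendar-year range; defaults to the
#'   span of the weather series.
#' @return A list of [run_season()] results, one per year, named by year.
#' @export
run_multi_year <- function(config, start_year = NULL, end_year = NULL) {
  yrs <- as.integer(format(config$weather$date, "%Y"))
  if (is.null(start_year)) start_year <- min(yrs)
  if (is.null(end_year)) end_year <- max(yrs)
  if (start_year < min(yrs) || end_year > max(yrs))
    stop("weather series does not cover ", start_year, "-", end_year)
  out <- lapply(start_year:end_year, function(y) {
    cfg <- config
    cfg$weather <- config$weather[yrs == y, , drop = FALSE]
    class(cfg$weather) <- c("weather_series", "data.frame")
    run_season(cfg)
  })
  names(out) <- as.character(start_year:end_year)
  out
}

#' Parameter sensitivity of the waterlogging functions
#'
#' For each stress function and each perturbation of +/-1 and +/-2 standard
#' deviations of its y parameters, runs the configured flood treatments over
#' multiple years and reports the percent change, relative to the default
#' parameterization and averaged over treatments and years, of yield,
#' biomass, N fixed, N uptake and maximum root depth. The fixation
#' function's saturated anchor (y = 0 at x = 1) is never adjusted.
#'
#' @param config a [sim_config()].
#' @param sd_table per-function y-parameter standard deviations
#'   (see [default_sd_table()]).
#' @param stages,durations the flood-treatment factorial averaged over.
#' @param functions subset of `c("photo", "pheno", "fix")`.
#' @return A data frame of class `sensitivity_table`: one row per function x
#'   perturbation with `d_yield_pct`, `d_biomass_pct`, `d_fixed_n_pct`,
#'   `d_uptake_n_pct`, `d_root_depth_pct` and a `pinned_anchor` flag.
#' @export
run_sensitivity <- function(config, sd_table = default_sd_table(),
                            stages = c("V4", "R2"), durations = c(2, 7, 14),
                            functions = c("photo", "pheno", "fix")) {
  yrs <- unique(as.integer(format(config$weather$date, "%Y")))
  run_set <- function(ox) {
    cfg <- config
    cfg$oxdef <- ox
    acc <- list()
    for (y in yrs) {
      sel <- as.integer(format(cfg$weather$date, "%Y")) == y
      yc <- cfg
      yc$weather <- cfg$weather[sel, , drop = FALSE]
      class(yc$weather) <- c("weather_series", "data.frame")
      for (s in stages) for (d in durations) {
        yc$treatments <- list(flood_treatment(trigger_stage = s,
                                              duration_days = d))
        r <- run_season(yc)
        acc[[length(acc) + 1L]] <- c(r$yield, r$biomass, r$cum_fixed_n,
                                     r$cum_uptake_n, r$max_root_depth)
      }
    }
    colMeans(do.call(rbind, acc))
  }
  ref <- run_set(config$oxdef)
  rows <- list()
  for (fn in functions) for (nsd in c(-2, -1, 1, 2)) {
    ox <- perturb_params(config$oxdef, fn, nsd, sd_table)
    v <- run_set(ox)
    pct <- ifelse(ref == 0, 0, 100 * (v - ref) / ref)
    rows[[length(rows) + 1L]] <- data.frame(
      fn = fn, n_sd = nsd,
      d_yield_pct = pct[1L], d_biomass_pct = pct[2L],
      d_fixed_n_pct = pct[3L], d_uptake_n_pct = pct[4L],
      d_root_depth_pct = pct[5L],
      pinned_anchor = fn == "fix")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Rainfall-scenario risk analysis
#'
#' Runs every year of the configured weather as a paired control vs
#' scenario comparison (shared pre-perturbation weather, soil and cultivar)
#' for each scenario and summarises the percent yield penalty.
#'
#' @param config a [sim_config()] (its `scenario` is replaced).
#' @param scenarios list of [climate_scenario()]; defaults to the eight
#'   built-in [risk_scenarios()].
#' @return A data frame of class `risk_summary`: per scenario the mean, sd,
#'   min and max percent yield penalty across years, plus a `yearly` attr
#'   with the per-year table.
#' @export
run_risk_analysis <- function(config, scenarios = risk_scenarios()) {
  yrs <- unique(as.integer(format(config$weather$date, "%Y")))
  yearly <- list()
  ctrl_yield <- numeric(length(yrs))
  ctrl_res <- list()
  for (j in seq_along(yrs)) {
    sel <- as.integer(format(config$weather$date, "%Y")) == yrs[j]
    yc <- config
    yc$weather <- config$weather[sel, , drop = FALSE]
    class(yc$weather) <- c("weather_series", "data.frame")
    yc$scenario <- NULL
    ctrl_res[[j]] <- yc
    ctrl_yield[j] <- run_season(yc)$yield
  }
  for (scn in scenarios) {
    pen <- numeric(length(yrs))
    for (j in seq_along(yrs)) {
      yc <- ctrl_res[[j]]
      yc$scenario <- scn
      pen[j] <- yield_penalty_percent(run_season(yc)$yield, ctrl_yield[j])
    }
    yearly[[scn$name]] <- data.frame(scenario = scn$name, year = yrs,
                                     control_yield = ctrl_yield,
                                     penalty_pct = pen)
  }
  tab <- do.call(rbind, lapply(yearly, function(d) data.frame(
    scenario = d$scenario[1L], mean_penalty_pct = mean(d$penalty_pct),
    sd_penalty_pct = stats::sd(d$penalty_pct),
    min_penalty_pct = min(d$penalty_pct),
    max_penalty_pct = max(d$penalty_pct), n_years = nrow(d))))
  rownames(tab) <- NULL
  attr(tab, "yearly") <- do.call(rbind, yearly)
  class(tab) <- c("risk_summary", "data.frame")
  tab
}
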