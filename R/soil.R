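#' Layered soil profile
#'
#' Layers are indexed top-down; depths are mm below the surface with
#' half-open layer intervals `[top, bottom)`. Water contents are volumetric
#' fractions with the usual ordering `ll15 < dul < sat`: `ll15` is the lower
#' limit of plant-extractable water, `dul` the drained upper limit (field
#' capacity, the zero-stress anchor of the excess-water functions) and `sat`
#' saturation (the full-stress anchor).
#'
#' @param thickness layer thicknesses (mm).
#' @param ll15,dul,sat volumetric water fractions per layer.
#' @param bd bulk density (g cm-3).
#' @param ks saturated drainage capacity to the layer below (mm d-1); the
#'   bottom layer's `ks` is the profile's deep-drainage capacity, and a small
#'   value there is what lets water tables perch.
#' @param kl per-layer fraction of plant-available water extractable per day;
#'   defaults to 0.10 at the surface decaying exponentially with depth.
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(thickness, ll15, dul, sat, bd = 1.3, ks = 20,
                         kl = NULL) {
  n <- length(thickness)
  rec <- function(x) rep_len(as.numeric(x), n)
  p <- list(thickness = rec(thickness), ll15 = rec(ll15), dul = rec(dul),
            sat = rec(sat), bd = rec(bd), ks = rec(ks))
  if (any(p$thickness <= 0)) stop("layer thickness must be positive")
  if (any(p$ks < 0)) stop("ks must be non-negative")
  bad <- which(!(p$ll15 > 0 & p$ll15 < p$dul & p$dul < p$sat & p$sat < 1))
  if (length(bad))
    stop("layer ", bad[1L], ": need 0 < ll15 < dul < sat < 1")
  depth_bottom <- cumsum(p$thickness)
  depth_top <- depth_bottom - p$thickness
  if (is.null(kl))
    kl <- 0.12 * exp(-(depth_top + p$thickness / 2) / 1100)
  p$kl <- rec(kl)
  p$depth_top <- depth_top
  p$depth_bottom <- depth_bottom
  p$depth <- depth_bottom[n]
  structure(p, class = "soil_profile")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat("soil_profile:", length(x$thickness), "layers,",
      x$depth, "mm deep\n")
  print(data.frame(top_mm = x$depth_top, thick_mm = x$thickness,
                   ll15 = x$ll15, dul = x$dul, sat = x$sat,
                   ks = x$ks, kl = round(x$kl, 3)))
  invisible(x)
}

# comparison tolerance for "saturated" (volumetric)
SAT_EPS <- 1e-4

#' Soil water state
#'
#' Per-layer volumetric water plus cumulative balance terms. All movement
#' operations preserve `ll15 - eps <= sw <= sat` and close the daily water
#' balance.
#'
#' @param profile a [soil_profile()].
#' @param sw initial volumetric water per layer; defaults to `dul`.
#' @param mineral_n initial mineral N per layer (kg N ha-1); defaults to 0.
#' @return An object of class `soil_water_state`.
#' @export
soil_water_state <- function(profile, sw = NULL, mineral_n = NULL) {
  n <- length(profile$thickness)
  if (is.null(sw)) sw <- profile$dul
  sw <- rep_len(as.numeric(sw), n)
  if (any(sw > profile$sat + SAT_EPS) || any(sw < profile$ll15 - SAT_EPS))
    stop("initial sw outside [ll15, sat]")
  if (is.null(mineral_n)) mineral_n <- numeric(n)
  structure(list(sw = pmin(sw, profile$sat), mineral_n = rep_len(mineral_n, n),
                 cum_drainage = 0, cum_runoff = 0, cum_evap = 0,
                 cum_transp = 0, cum_flood_water = 0),
            class = "soil_water_state")
}

stored_water <- function(profile, state) sum(state$sw * profile$thickness)

#' One daily step of the tipping-bucket water balance
#'
#' Cascade order: ponded daily rain infiltrates top-down, filling each
#' layer to saturation (only rain beyond the whole profile's remaining pore
#' space becomes runoff); each layer then drains water above `dul` downward
#' at most `ks` mm, limited by the receiving layer's remaining capacity to
#' `sat`, with bottom-layer outflow becoming deep drainage. Excess water
#' (above `dul`) still held after drainage redistributes onto the impeding
#' bottom of the profile, so perched water tables rise from the bottom up
#' and fall from the top as the excess drains. Soil evaporation is taken
#' from layer 1 down to `ll15`; per-layer transpiration is subtracted last.
#'
#' @param profile a [soil_profile()].
#' @param state a [soil_water_state()].
#' @param rain_mm rainfall reaching the surface (mm).
#' @param soil_evap_demand_mm potential soil evaporation (mm).
#' @param transpiration_by_layer_mm numeric per-layer transpiration (mm);
#'   must not exceed the plant-available water of each layer.
#' @return The updated `soil_water_state`.
#' @export
step_water_balance <- function(profile, state, rain_mm,
                               soil_evap_demand_mm = 0,
                               transpiration_by_layer_mm = 0) {
  if (rain_mm < 0 || soil_evap_demand_mm < 0 ||
      any(transpiration_by_layer_mm < 0))
    stop("water balance inputs must be non-negative")
  n <- length(profile$thickness)
  th <- profile$thickness
  sw_mm <- state$sw * th
  dul_mm <- profile$dul * th
  sat_mm <- profile$sat * th
  ll_mm <- profile$ll15 * th

  # ponded infiltration, filling layers top-down to saturation
  left <- rain_mm
  for (i in seq_len(n)) {
    take <- min(left, max(0, sat_mm[i] - sw_mm[i]))
    sw_mm[i] <- sw_mm[i] + take
    left <- left - take
    if (left <= 0) break
  }
  runoff <- left

  # gravity drainage, top-down
  drainage <- 0
  for (i in seq_len(n)) {
    excess <- max(0, sw_mm[i] - dul_mm[i])
    flux <- min(excess, profile$ks[i])
    if (i < n) flux <- min(flux, max(0, sat_mm[i + 1L] - sw_mm[i + 1L]))
    sw_mm[i] <- sw_mm[i] - flux
    if (i < n) sw_mm[i + 1L] <- sw_mm[i + 1L] + flux else drainage <- flux
  }

  # perched-table redistribution: excess above dul pools on the impeding
  # bottom of the profile, saturating layers from the bottom up
  pool <- sum(pmax(0, sw_mm - dul_mm))
  if (pool > 1e-12) {
    sw_mm <- pmin(sw_mm, dul_mm)
    for (i in n:1) {
      put <- min(pool, sat_mm[i] - sw_mm[i])
      sw_mm[i] <- sw_mm[i] + put
      pool <- pool - put
      if (pool <= 1e-12) break
    }
  }

  # surface evaporation from layer 1
  evap <- min(soil_evap_demand_mm, max(0, sw_mm[1L] - ll_mm[1L]))
  sw_mm[1L] <- sw_mm[1L] - evap

  # transpiration extraction
  tr <- rep_len(transpiration_by_layer_mm, n)
  avail <- pmax(0, sw_mm - ll_mm)
  if (any(tr > avail + 1e-9))
    stop("transpiration exceeds plant-available water in a layer")
  sw_mm <- sw_mm - tr

  state$sw <- sw_mm / th
  state$cum_runoff <- state$cum_runoff + runoff
  state$cum_drainage <- state$cum_drainage + drainage
  state$cum_evap <- state$cum_evap + evap
  state$cum_transp <- state$cum_transp + sum(tr)
  state
}

#' Depth to the perched water table
#'
#' The table is the top of the contiguous block of saturated layers
#' (`sw >= sat - eps`) anchored at the bottom of the profile; saturated
#' lenses above unsaturated soil do not define a table. Returns the full
#' profile depth when the bottom layer is unsaturated.
#'
#' @param profile a [soil_profile()].
#' @param state a [soil_water_state()].
#' @return Depth in mm below the surface (0 = table at the surface).
#' @export
water_table_depth <- function(profile, state) {
  n <- length(profile$thickness)
  satd <- state$sw >= profile$sat - SAT_EPS
  if (!satd[n]) return(profile$depth)
  i <- n
  while (i > 1L && satd[i - 1L]) i <- i - 1L
  profile$depth_top[i]
}

#' Force the profile to full saturation (flooding)
#'
#' Emulates adding excess water until the water table reaches the surface on
#' a flood-treatment day. Every layer is set to `sat`; the water added is
#' logged in `cum_flood_water` so the balance ledger still closes.
#'
#' @param profile a [soil_profile()].
#' @param state a [soil_water_state()].
#' @return The saturated `soil_water_state` (idempotent).
#' @export
force_flood <- function(profile, state) {
  added <- sum(pmax(0, profile$sat - state$sw) * profile$thickness)
  state$sw <- profile$sat
  state$cum_flood_water <- state$cum_flood_water + added
  state
}

#' Fraction of the root system below the water table
#'
#' @param root_depth_mm rooting depth (mm, > 0).
#' @param water_table_depth_mm water-table depth (mm below surface).
#' @return `max(0, (root_depth - water_table)/root_depth)` clamped to [0, 1];
#'   the predictor of the photosynthesis and phenology waterlogging stresses.
#' @export
fraction_roots_submerged <- function(root_depth_mm, water_table_depth_mm) {
  if (any(root_depth_mm <= 0)) stop("root depth must be positive")
  pmin(1, pmax(0, (root_depth_mm - water_table_depth_mm) / root_depth_mm))
}

#' Water-filled-pore-space excess fraction of the nodule zone
#'
#' Thickness-weighted mean over the layers above `activation_depth_mm`
#' (default 450 mm, the depth holding most active nodules) of
#' `clamp((sw - dul)/(sat - dul), 0, 1)`: 0 at field capacity, 1 at
#' saturation. Predictor of the N-fixation waterlogging stress.
#'
#' @param profile a [soil_profile()].
#' @param state a [soil_water_state()].
#' @param activation_depth_mm depth of the nodule zone (mm, user-definable).
#' @return A fraction in [0, 1].
#' @export
wfps_excess_fraction <- function(profile, state, activation_depth_mm = 450) {
  if (activation_depth_mm <= 0) stop("activation depth must be positive")
  tin <- pmax(0, pmin(profile$depth_bottom, activation_depth_mm) -
                 profile$depth_top)
  if (sum(tin) == 0) return(0)
  x <- pmin(1, pmax(0, (state$sw - profile$dul) / (profile$sat - profile$dul)))
  sum(x * tin) / sum(tin)
}

#' Plant-available root-zone water supply
#'
#' Sums `thickness_in_rootzone * max(0, sw - ll15) * kl` over layers
#' intersecting the root zone, excluding layers saturated with water
#' (`sw >= sat - eps`): roots cease resource uptake from saturated layers.
#'
#' @param profile a [soil_profile()].
#' @param state a [soil_water_state()].
#' @param root_depth_mm rooting depth (mm).
#' @return Supply in mm d-1.
#' @export
available_supply <- function(profile, state, root_depth_mm) {
  if (root_depth_mm < 0) stop("root depth must be non-negative")
  tin <- pmax(0, pmin(profile$depth_bottom, root_depth_mm) - profile$depth_top)
  satd <- state$sw >= profile$sat - SAT_EPS
  sum(ifelse(satd, 0, tin * pmax(0, state$sw - profile$ll15) * profile$kl))
}

#' Air-filled porosity at a depth
#'
#' `sat - sw` of the layer containing `depth_mm`. Root elongation is arrested
#' below 3 percent air-filled porosity.
#'
#' @param profile a [soil_profile()].
#' @param state a [soil_water_state()].
#' @param depth_mm depth below the surface (mm), within the profile.
#' @return Volumetric air-filled porosity (fraction).
#' @export
air_filled_porosity_at <- function(profile, state, depth_mm) {
  if (depth_mm < 0 || depth_mm > profile$depth)
    stop("depth ", depth_mm, " mm is outside the profile")
  i <- findInterval(depth_mm, profile$depth_top,
                    rightmost.closed = FALSE, left.open = FALSE)
  i <- max(1L, min(i, length(profile$thickness)))
  profile$sat[i] - state$sw[i]
}
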