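#' Piecewise-linear 0-1 stress multiplier ("x/y pairs")
#'
#' The common currency of the moisture stress framework: a response function
#' given as x/y pairs, where x is the stress predictor (e.g. the fraction of
#' roots submerged) and y the multiplier applied to a process rate.
#'
#' @param xs strictly increasing predictor values (length >= 2).
#' @param ys multipliers in [0, 1], same length as `xs`.
#' @return An object of class `piecewise_multiplier`.
#' @export
piecewise_multiplier <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) < 2 || length(xs) != length(ys))
    stop("need >= 2 x/y pairs of equal length")
  if (any(diff(xs) <= 0)) stop("xs must be strictly increasing")
  if (any(ys < 0 | ys > 1)) stop("ys must lie in [0, 1]")
  structure(list(xs = xs, ys = ys), class = "piecewise_multiplier")
}

#' Evaluate an x/y-pair multiplier
#'
#' Linear interpolation between bracketing pairs, clamped to the endpoint
#' multipliers outside the x range.
#'
#' @param fn a [piecewise_multiplier()].
#' @param x predictor value(s).
#' @return Multiplier(s) in [0, 1].
#' @export
evaluate_multiplier <- function(fn, x) {
  stopifnot(inherits(fn, "piecewise_multiplier"))
  stats::approx(fn$xs, fn$ys, xout = x, rule = 2)$y
}

#' Supply/demand drought stress on photosynthesis
#'
#' Should the root-zone water supply to transpiration-demand ratio fall
#' below 1 there is drought stress; at or above 1 there is none.
#'
#' @param supply_mm daily root-zone water supply (mm).
#' @param demand_mm daily transpiration demand (mm).
#' @return `min(1, supply/demand)`; 1 when demand is 0.
#' @export
drought_photo_stress <- function(supply_mm, demand_mm) {
  if (any(supply_mm < 0) || any(demand_mm < 0))
    stop("supply and demand must be non-negative")
  ifelse(demand_mm == 0, 1, pmin(1, supply_mm / demand_mm))
}

#' Stage-dependent severity of waterlogging stress
#'
#' Waterlogging is more damaging during reproductive stages. Severity `S`
#' multiplies the stress depth `1 - y`: it ramps linearly from
#' `severity_veg` (before `sensitive_stage_start`, default R1) to
#' `severity_rep` at pod-fill onset (R3) and stays there.
#'
#' @param sensitive_stage_start stage code where the ramp begins (user
#'   defined; default 3 = R1).
#' @param severity_veg,severity_rep dimensionless severity factors,
#'   `severity_rep >= severity_veg >= 0`.
#' @return An object of class `stage_severity`.
#' @export
stage_severity <- function(sensitive_stage_start = 3, severity_veg = 1,
                           severity_rep = 1.2) {
  if (severity_veg < 0 || severity_rep < severity_veg)
    stop("need 0 <= severity_veg <= severity_rep")
  structure(list(sensitive_stage_start = sensitive_stage_start,
                 severity_veg = severity_veg, severity_rep = severity_rep),
            class = "stage_severity")
}

severity_at <- function(stage, stage_code) {
  s0 <- stage$sensitive_stage_start
  s1 <- STAGE_R3   # pod-fill onset ends the ramp
  f <- if (s1 <= s0) as.numeric(stage_code >= s0)
       else pmin(1, pmax(0, (stage_code - s0) / (s1 - s0)))
  stage$severity_veg + f * (stage$severity_rep - stage$severity_veg)
}

#' Amplify a stress multiplier by stage severity
#'
#' @param base_y base multiplier in [0, 1].
#' @param stage_code continuous stage code (see [crop_state()]).
#' @param stage a [stage_severity()].
#' @return `clamp(1 - (1 - base_y) * S(stage_code), 0, 1)`.
#' @export
apply_stage_severity <- function(base_y, stage_code, stage) {
  if (any(base_y < 0 | base_y > 1)) stop("base_y must lie in [0, 1]")
  pmin(1, pmax(0, 1 - (1 - base_y) * severity_at(stage, stage_code)))
}

#' Waterlogging ("oxygen deficit") stress parameter set
#'
#' Bundles the three stress response functions, their shared stage severity,
#' the nodule-zone activation depth, and the post-flood recovery persistence.
#' The defaults are pinned to the literature anchors: photosynthesis and
#' phenology respond only once 80 percent of the roots are submerged;
#' N fixation responds above a water-filled-pore-space excess of 0.5 and
#' stops completely at saturation.
#'
#' @param photo x/y pairs over fraction-of-roots-submerged for the
#'   radiation-use-efficiency multiplier.
#' @param pheno x/y pairs over fraction-of-roots-submerged for the
#'   development-rate multiplier.
#' @param fix x/y pairs over the nodule-zone WFPS-excess fraction for the
#'   N-fixation multiplier; the y value at x = 1 must be 0.
#' @param stage a [stage_severity()].
#' @param fix_activation_depth nodule-zone depth (mm, default 450).
#' @param recovery_persistence fraction of the worst in-flood stress retained
#'   after a flood that occurred at or after R1 (default 0.5); floods ending
#'   before R1 leave no carry-over.
#' @param pheno_rep_relief severity multiplier applied to the development
#'   stall at reproductive stages (ramping in from `sensitive_stage_start`
#'   to pod-fill onset). Vegetative floods stall development fully, but
#'   flooded reproductive plants keep progressing towards maturity, so the
#'   stall depth is relieved (default 0.4).
#' @param enabled if `FALSE` all three functions return 1 (the original,
#'   pre-improvement model).
#' @return An object of class `oxdef_params`.
#' @export
oxdef_params <- function(photo = piecewise_multiplier(c(0, 0.8, 1),
                                                      c(1, 1, 0.75)),
                         pheno = piecewise_multiplier(c(0, 0.8, 1),
                                                      c(1, 1, 0.4)),
                         fix = piecewise_multiplier(c(0, 0.5, 1),
                                                    c(1, 1, 0)),
                         stage = stage_severity(),
                         fix_activation_depth = 450,
                         recovery_persistence = 0.5,
                         pheno_rep_relief = 0.4,
                         enabled = TRUE) {
  if (tail1(fix$ys) != 0)
    stop("the fixation function must have y = 0 at x = 1 ",
         "(N fixation stops in saturated soil)")
  if (fix_activation_depth <= 0) stop("fix_activation_depth must be positive")
  if (recovery_persistence < 0 || recovery_persistence > 1)
    stop("recovery_persistence must lie in [0, 1]")
  if (pheno_rep_relief < 0 || pheno_rep_relief > 1)
    stop("pheno_rep_relief must lie in [0, 1]")
  structure(list(photo = photo, pheno = pheno, fix = fix, stage = stage,
                 fix_activation_depth = fix_activation_depth,
                 recovery_persistence = recovery_persistence,
                 pheno_rep_relief = pheno_rep_relief,
                 enabled = isTRUE(enabled)),
            class = "oxdef_params")
}

tail1 <- function(x) x[length(x)]

#' Waterlogging stress on photosynthesis (RUE multiplier)
#'
#' @param frac_submerged fraction of roots below the water table (0-1).
#' @param stage_code continuous stage code.
#' @param params an [oxdef_params()].
#' @return Multiplier in [0, 1]; 1 whenever `params$enabled` is `FALSE`.
#' @export
oxdef_photo <- function(frac_submerged, stage_code, params = oxdef_params()) {
  if (!params$enabled) return(rep_len(1, length(frac_submerged)))
  apply_stage_severity(evaluate_multiplier(params$photo, frac_submerged),
                       stage_code, params$stage)
}

#' Waterlogging stress on phenological development
#'
#' Scales daily thermal-time accumulation; full submergence stalls
#' development to 40 percent of potential by default during the vegetative
#' phase. The stall is relieved at reproductive stages
#' (`pheno_rep_relief`): a flooded reproductive crop keeps progressing
#' towards maturity while its assimilation and N supply are suppressed, so
#' the pod-set window is genuinely lost rather than merely postponed.
#'
#' @inheritParams oxdef_photo
#' @return Multiplier in [0, 1].
#' @export
oxdef_pheno <- function(frac_submerged, stage_code, params = oxdef_params()) {
  if (!params$enabled) return(rep_len(1, length(frac_submerged)))
  base <- evaluate_multiplier(params$pheno, frac_submerged)
  s0 <- params$stage$sensitive_stage_start
  f <- pmin(1, pmax(0, (stage_code - s0) / max(1e-9, STAGE_R3 - s0)))
  sev <- params$stage$severity_veg * (1 + f * (params$pheno_rep_relief - 1))
  pmin(1, pmax(0, 1 - (1 - base) * sev))
}

#' Waterlogging stress on symbiotic N fixation
#'
#' Driven by the nodule-zone WFPS-excess fraction; the saturation anchor
#' (x = 1, y = 0) is pinned at every stage — fixation stops in saturated
#' soil regardless of severity.
#'
#' @param wfps_excess nodule-zone WFPS-excess fraction (0-1).
#' @inheritParams oxdef_photo
#' @return Multiplier in [0, 1]; exactly 0 at `wfps_excess = 1`.
#' @export
oxdef_fix <- function(wfps_excess, stage_code, params = oxdef_params()) {
  if (!params$enabled) return(rep_len(1, length(wfps_excess)))
  y <- apply_stage_severity(evaluate_multiplier(params$fix, wfps_excess),
                            stage_code, params$stage)
  ifelse(wfps_excess >= 1, 0, y)
}

#' Post-flood recovery carry-over
#'
#' Plants fully recover from floods that end before R1, but floods at or
#' after R1 leave a lasting depression: until maturity the effective
#' multiplier is capped at `1 - persistence * (1 - worst in-flood value)`.
#'
#' @param stress_today today's raw stress multiplier (0-1).
#' @param flood_active `TRUE` while the water table is within the root zone.
#' @param stage_code continuous stage code.
#' @param params an [oxdef_params()] (supplies `recovery_persistence`).
#' @param carry_state list with `min_mult` (worst multiplier in the most
#'   recent flood) and `max_stage` (latest stage reached during it); use
#'   [new_carry_state()] to start a season.
#' @return List with `mult` (effective multiplier) and `carry` (updated
#'   state).
#' @export
post_flood_recovery <- function(stress_today, flood_active, stage_code,
                                params, carry_state = new_carry_state()) {
  if (flood_active) {
    carry_state$min_mult <- min(carry_state$min_mult, stress_today)
    carry_state$max_stage <- max(carry_state$max_stage, stage_code)
    return(list(mult = stress_today, carry = carry_state))
  }
  cap <- 1
  if (carry_state$max_stage >= STAGE_R1 && carry_state$min_mult < 1)
    cap <- 1 - params$recovery_persistence * (1 - carry_state$min_mult)
  list(mult = min(stress_today, cap), carry = carry_state)
}

#' @rdname post_flood_recovery
#' @export
new_carry_state <- function() list(min_mult = 1, max_stage = -Inf)

#' Perturb one stress function's y parameters (sensitivity analysis)
#'
#' Shifts the adjustable y values of the chosen function by `n_sd` standard
#' deviations, clamping to [0, 1]. The leading y (the no-stress anchor at
#' x = 0) is never adjusted, and for the fixation function the y value at
#' x = 1 is held at 0: N fixation stops when soils are fully saturated.
#'
#' @param params an [oxdef_params()].
#' @param which_function `"photo"`, `"pheno"` or `"fix"`.
#' @param n_sd number of standard deviations (-2, -1, +1, +2).
#' @param sd_table named list/vector of per-function standard deviations of
#'   the y parameters (default 0.05 each, user-overridable).
#' @return A perturbed copy of `params`.
#' @export
perturb_params <- function(params, which_function = c("photo", "pheno", "fix"),
                           n_sd, sd_table = default_sd_table()) {
  which_function <- match.arg(which_function)
  sdv <- sd_table[[which_function]]
  fn <- params[[which_function]]
  ys <- fn$ys
  adj <- seq_along(ys) > 1L           # x = 0 anchor untouched
  if (which_function == "fix") adj[length(ys)] <- FALSE  # pinned y(1) = 0
  ys[adj] <- pmin(1, pmax(0, ys[adj] + n_sd * sdv))
  if (any(diff(ys[fn$xs >= min(fn$xs)]) > 0 & diff(fn$ys) <= 0)) {
    # keep the perturbed function monotone where the default was
    for (i in seq_along(ys)[-1L])
      if (fn$ys[i] <= fn$ys[i - 1L] && ys[i] > ys[i - 1L]) {
        ys[i] <- ys[i - 1L]
        warning("perturbation clamped to preserve monotonicity of '",
                which_function, "'")
      }
  }
  params[[which_function]] <- piecewise_multiplier(fn$xs, ys)
  params
}

#' @rdname perturb_params
#' @export
default_sd_table <- function() list(photo = 0.05, pheno = 0.05, fix = 0.05)
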