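#' Read and write soil profile files
#'
#' Soil profiles are stored as YAML: an ordered list of layer records with
#' `thickness`, `ll15`, `dul`, `sat`, `bd`, `ks` and optionally `kl`.
#'
#' @param path file path.
#' @return `read_soil_profile()`: a [soil_profile()].
#' @export
read_soil_profile <- function(path) {
  y <- yaml::read_yaml(path)
  lay <- y$layers
  get <- function(f) vapply(lay, function(l) as.numeric(l[[f]]), numeric(1))
  kl <- if (all(vapply(lay, function(l) !is.null(l$kl), logical(1))))
    get("kl") else NULL
  tryCatch(
    soil_profile(get("thickness"), get("ll15"), get("dul"), get("sat"),
                 get("bd"), get("ks"), kl),
    error = function(e) stop("invalid soil profile in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' @rdname read_soil_profile
#' @param profile a [soil_profile()].
#' @export
write_soil_profile <- function(profile, path) {
  layers <- lapply(seq_along(profile$thickness), function(i)
    list(thickness = profile$thickness[i], ll15 = profile$ll15[i],
         dul = profile$dul[i], sat = profile$sat[i], bd = profile$bd[i],
         ks = profile$ks[i], kl = profile$kl[i]))
  yaml::write_yaml(list(layers = layers), path)
  invisible(path)
}

#' Read and write cultivar parameter files
#'
#' @param path file path.
#' @return `read_cultivar()`: a [cultivar()].
#' @export
read_cultivar <- function(path) {
  y <- yaml::read_yaml(path)
  tt <- unlist(y$tt_targets)
  y$tt_targets <- NULL
  do.call(cultivar, c(list(tt_targets = tt), y))
}

#' @rdname read_cultivar
#' @param cv a [cultivar()].
#' @export
write_cultivar <- function(cv, path) {
  out <- unclass(cv)
  out$tt_targets <- as.list(cv$tt_targets)
  yaml::write_yaml(out, path)
  invisible(path)
}

parse_multiplier <- function(x) piecewise_multiplier(
  vapply(x, function(p) as.numeric(p[[1L]]), numeric(1)),
  vapply(x, function(p) as.numeric(p[[2L]]), numeric(1)))

#' Read a run configuration file
#'
#' A YAML file with sections `weather` (path + dialect, or `synthetic` with
#' climate parameters and `n_years`), `soil` (path), `cultivar` (path or
#' `preset`), `run` (`sowing`, `seed`, `init_mineral_n`,
#' `mineralization_rate`), optional `oxdef` (`enable_oxdef`, x/y `pairs` per
#' function, `stage`, `recovery_persistence`, `fix_activation_depth`),
#' optional `treatment`(s) and optional `scenario`. Relative paths are
#' resolved against the config file's directory.
#'
#' @param path path to the YAML config.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  seed <- as.integer(y$run$seed %||% 1L)

  ws <- if (!is.null(y$weather$path)) {
    read_weather(rel(y$weather$path), y$weather$dialect %||% "csv")
  } else if (!is.null(y$weather$synthetic)) {
    s <- y$weather$synthetic
    cp <- climate_params(
      tmean_annual = s$tmean_annual %||% 16, tamp = s$tamp %||% 11,
      trange = s$trange %||% 10, radn_mean = s$radn_mean %||% 16,
      radn_amp = s$radn_amp %||% 8,
      rain_monthly = unlist(s$rain_monthly %||% rep(80, 12)),
      p_wd = s$p_wd %||% 0.25, p_ww = s$p_ww %||% 0.45)
    generate_synthetic_weather(cp, seed, s$n_years %||% 1,
                               s$start_year %||% 1991)
  } else stop("config must give weather$path or weather$synthetic")

  profile <- read_soil_profile(rel(y$soil$path))
  cv <- if (!is.null(y$cultivar$preset)) cultivar_preset(y$cultivar$preset)
        else read_cultivar(rel(y$cultivar$path))

  ox_args <- list()
  oxy <- y$oxdef
  if (!is.null(oxy)) {
    if (!is.null(oxy$photo)) ox_args$photo <- parse_multiplier(oxy$photo)
    if (!is.null(oxy$pheno)) ox_args$pheno <- parse_multiplier(oxy$pheno)
    if (!is.null(oxy$fix)) ox_args$fix <- parse_multiplier(oxy$fix)
    if (!is.null(oxy$stage))
      ox_args$stage <- stage_severity(
        oxy$stage$sensitive_stage_start %||% 3,
        oxy$stage$severity_veg %||% 1, oxy$stage$severity_rep %||% 1.2)
    if (!is.null(oxy$fix_activation_depth))
      ox_args$fix_activation_depth <- oxy$fix_activation_depth
    if (!is.null(oxy$recovery_persistence))
      ox_args$recovery_persistence <- oxy$recovery_persistence
    if (!is.null(oxy$enable_oxdef)) ox_args$enabled <- oxy$enable_oxdef
  }
  ox <- do.call(oxdef_params, ox_args)

  trs <- y$treatment %||% y$treatments
  if (!is.null(trs) && !is.null(trs$duration_days)) trs <- list(trs)
  treatments <- lapply(trs %||% list(), function(tr)
    flood_treatment(trigger_stage = tr$trigger_stage,
                    trigger_doy = tr$trigger_doy,
                    duration_days = tr$duration_days %||% 0))

  scn <- NULL
  if (!is.null(y$scenario))
    scn <- climate_scenario(
      kind = y$scenario$kind %||% "none",
      months = unlist(y$scenario$months %||% integer()),
      scale_factor = y$scenario$scale_factor %||% 1,
      event_depth = y$scenario$event_depth %||% 0,
      events_per_month = y$scenario$events_per_month %||% 0)

  sim_config(weather = ws, profile = profile, cv = cv,
             sowing_doy = y$run$sowing %||% "05-15", oxdef = ox,
             treatments = treatments, scenario = scn,
             init_mineral_n = y$run$init_mineral_n %||% 60,
             mineralization_rate = y$run$mineralization_rate %||% 0.8,
             seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
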