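#' Daily weather series
#'
#' A `weather_series` is a data frame with one row per calendar day and
#' columns `date` (class `Date`, strictly increasing and gap-free),
#' `tmax`/`tmin` (degrees C), `radn` (MJ m-2 d-1 incident shortwave) and
#' `rain` (mm d-1). It is the daily driver of every simulation and the
#' object that climate scenarios perturb.
#'
#' @param date vector of `Date` (or coercible strings).
#' @param tmax,tmin daily maximum and minimum air temperature (degrees C).
#' @param radn daily incident solar radiation (MJ m-2 d-1).
#' @param rain daily rainfall (mm).
#' @return A validated `weather_series` data frame.
#' @export
weather_series <- function(date, tmax, tmin, radn, rain) {
  ws <- data.frame(date = as.Date(date), tmax = as.numeric(tmax),
                   tmin = as.numeric(tmin), radn = as.numeric(radn),
                   rain = as.numeric(rain))
  class(ws) <- c("weather_series", "data.frame")
  validate_weather(ws)
}

validate_weather <- function(ws) {
  need <- c("date", "tmax", "tmin", "radn", "rain")
  miss <- setdiff(need, names(ws))
  if (length(miss))
    stop("weather series is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(ws[need]))
    stop("weather series contains missing values")
  d <- as.integer(diff(ws$date))
  if (length(d) && any(d != 1L)) {
    i <- which(d != 1L)[1L]
    stop("weather dates must be strictly increasing and gap-free; break after ",
         ws$date[i])
  }
  bad <- which(ws$tmax < ws$tmin)
  if (length(bad))
    stop("tmax < tmin on ", ws$date[bad[1L]])
  if (any(ws$radn < 0)) stop("negative radiation on ",
                             ws$date[which(ws$radn < 0)[1L]])
  if (any(ws$rain < 0)) stop("negative rainfall on ",
                             ws$date[which(ws$rain < 0)[1L]])
  ws
}

#' Read a daily weather file
#'
#' Two dialects are supported: plain CSV with columns
#' `date,tmax,tmin,radn,rain` (ISO-8601 dates), and a met-like
#' whitespace-delimited dialect with a header line of column names
#' (`year day radn maxt mint rain`), a units line in parentheses, and one
#' row per day (`day` is the day of year).
#'
#' @param path path to the file.
#' @param dialect `"csv"` or `"met"`.
#' @return A [weather_series()].
#' @export
read_weather <- function(path, dialect = c("csv", "met")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("weather file not found: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(weather_series(df$date, df$tmax, df$tmin, df$radn, df$rain))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[!#]", lines) & nzchar(trimws(lines))]
  hdr_i <- grep("^\\s*year\\s+day\\s", lines)[1L]
  if (is.na(hdr_i)) stop("met-like file lacks a 'year day ...' header: ", path)
  cols <- strsplit(trimws(lines[hdr_i]), "\\s+")[[1L]]
  body <- lines[-seq_len(hdr_i)]
  body <- body[!grepl("^\\s*\\(", body)]   # units line(s)
  mat <- utils::read.table(text = body, col.names = cols)
  date <- as.Date(mat$day - 1L, origin = paste0(mat$year, "-01-01"))
  weather_series(date, mat$maxt, mat$mint, mat$radn, mat$rain)
}

#' Write a daily weather file
#'
#' @inheritParams read_weather
#' @param ws a [weather_series()].
#' @return `path`, invisibly.
#' @export
write_weather <- function(ws, path, dialect = c("csv", "met")) {
  dialect <- match.arg(dialect)
  ws <- validate_weather(ws)
  if (dialect == "csv") {
    utils::write.csv(as.data.frame(ws), path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  yr <- as.integer(format(ws$date, "%Y"))
  doy <- as.integer(format(ws$date, "%j"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("year day radn maxt mint rain",
               "()   ()  (MJ/m^2) (oC) (oC) (mm)"), con)
  writeLines(sprintf("%d %d %.3f %.2f %.2f %.3f",
                     yr, doy, ws$radn, ws$tmax, ws$tmin, ws$rain), con)
  invisible(path)
}

#' Climate parameters for the synthetic weather generator
#'
#' Defines a sinusoidal mean annual cycle for temperature and radiation and a
#' two-state (wet/dry) Markov rainfall model with monthly mean depths. The
#' generator stands in for reanalysis weather so every run is offline.
#'
#' @param tmean_annual annual mean of daily mean temperature (degrees C).
#' @param tamp seasonal half-amplitude of the mean temperature cycle (degrees C).
#' @param trange mean diurnal range, `tmax - tmin` (degrees C).
#' @param radn_mean,radn_amp annual mean and half-amplitude of daily solar
#'   radiation (MJ m-2 d-1).
#' @param rain_monthly numeric vector of length 12, target mean monthly
#'   rainfall totals (mm).
#' @param p_wd probability a wet day follows a dry day.
#' @param p_ww probability a wet day follows a wet day.
#' @param t_noise_sd standard deviation of day-to-day temperature noise
#'   (degrees C).
#' @param peak_doy day of year of the warmest mean temperature.
#' @param radn_peak_doy day of year of peak radiation (the solstice; thermal
#'   inertia makes temperature peak later).
#' @return An object of class `climate_params`.
#' @export
climate_params <- function(tmean_annual = 16, tamp = 11, trange = 10,
                           radn_mean = 16, radn_amp = 8,
                           rain_monthly = rep(80, 12),
                           p_wd = 0.25, p_ww = 0.45,
                           t_noise_sd = 1.5, peak_doy = 200, radn_peak_doy = 172) {
  stopifnot(length(rain_monthly) == 12, all(rain_monthly >= 0),
            p_wd >= 0, p_wd <= 1, p_ww >= 0, p_ww <= 1, trange > 0)
  structure(list(tmean_annual = tmean_annual, tamp = tamp, trange = trange,
                 radn_mean = radn_mean, radn_amp = radn_amp,
                 rain_monthly = rain_monthly, p_wd = p_wd, p_ww = p_ww,
                 t_noise_sd = t_noise_sd, peak_doy = peak_doy,
                 radn_peak_doy = radn_peak_doy),
            class = "climate_params")
}

#' Generate a synthetic multi-year weather series
#'
#' Temperature and radiation follow the sinusoidal annual cycle in `cp` with
#' AR(1) day-to-day noise; rainfall occurrence follows a two-state Markov
#' chain and wet-day depths are exponential, scaled so long-run monthly means
#' match `cp$rain_monthly`.
#'
#' @param cp a [climate_params()] object.
#' @param seed integer seed; the same seed always reproduces the same series.
#' @param n_years number of calendar years (>= 1).
#' @param start_year first calendar year.
#' @return A [weather_series()] covering Jan 1 of `start_year` through Dec 31
#'   of the last year.
#' @export
generate_synthetic_weather <- function(cp, seed, n_years, start_year = 1991) {
  stopifnot(inherits(cp, "climate_params"))
  if (n_years < 1) stop("n_years must be >= 1")
  dates <- seq(as.Date(paste0(start_year, "-01-01")),
               as.Date(paste0(start_year + n_years - 1L, "-12-31")), by = "day")
  n <- length(dates)
  mon <- as.integer(format(dates, "%m"))
  doy <- as.integer(format(dates, "%j"))
  with_seed(seed, {
    cyc <- cos(2 * pi * (doy - cp$peak_doy) / 365.25)
    noise <- stats::filter(stats::rnorm(n, 0, cp$t_noise_sd), 0.6,
                           method = "recursive")
    tmean <- cp$tmean_annual + cp$tamp * cyc + as.numeric(noise)
    tmax <- tmean + cp$trange / 2
    tmin <- tmean - cp$trange / 2
    rcyc <- cos(2 * pi * (doy - cp$radn_peak_doy) / 365.25)
    radn <- pmax(1, cp$radn_mean + cp$radn_amp * rcyc +
                   stats::rnorm(n, 0, 1.2))
    # stationary wet-day probability of the 2-state chain
    p_wet <- cp$p_wd / (1 + cp$p_wd - cp$p_ww)
    mdays <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
    depth_mean <- cp$rain_monthly / (mdays * p_wet)  # per wet day
    wet <- logical(n)
    u <- stats::runif(n)
    wet[1L] <- u[1L] < p_wet
    for (i in 2:n) {
      p <- if (wet[i - 1L]) cp$p_ww else cp$p_wd
      wet[i] <- u[i] < p
    }
    rain <- ifelse(wet, stats::rexp(n, 1) * depth_mean[mon], 0)
    weather_series(dates, tmax, tmin, radn, rain)
  })
}

#' Climate-change rainfall scenario
#'
#' Either a monthly multiplicative rainfall increase (`kind = "monthly_scale"`),
#' a set of fixed-depth extreme rain events added on evenly spaced days of the
#' named months (`kind = "extreme_events"`), or the identity (`kind = "none"`).
#'
#' @param kind `"none"`, `"monthly_scale"` or `"extreme_events"`.
#' @param months integer calendar months (1-12) the scenario touches.
#' @param scale_factor rainfall multiplier for `monthly_scale` (e.g. 1.25).
#' @param event_depth depth of each added extreme event (mm, e.g. 50).
#' @param events_per_month number of events per named month (0-4).
#' @param name optional label used in scenario tables.
#' @return An object of class `climate_scenario`.
#' @export
climate_scenario <- function(kind = c("none", "monthly_scale", "extreme_events"),
                             months = integer(), scale_factor = 1,
                             event_depth = 0, events_per_month = 0,
                             name = NULL) {
  kind <- match.arg(kind)
  stopifnot(scale_factor > 0, event_depth >= 0, events_per_month >= 0,
            all(months %in% 1:12))
  if (is.null(name)) {
    name <- switch(kind,
      none = "control",
      monthly_scale = paste0("x", scale_factor, "_m",
                             paste(months, collapse = "")),
      extreme_events = paste0("ev", events_per_month, "x", event_depth, "mm"))
  }
  structure(list(kind = kind, months = as.integer(months),
                 scale_factor = scale_factor, event_depth = event_depth,
                 events_per_month = as.integer(events_per_month), name = name),
            class = "climate_scenario")
}

#' Multiply rainfall in selected months
#'
#' Rain on every day of the named months is multiplied by `scale_factor`;
#' temperature, radiation and all other days are untouched.
#'
#' @param ws a [weather_series()].
#' @param months integer months (1-12); empty set is the identity.
#' @param scale_factor positive multiplier.
#' @return The perturbed [weather_series()].
#' @export
apply_monthly_rain_increase <- function(ws, months, scale_factor) {
  stopifnot(scale_factor > 0)
  ws <- validate_weather(ws)
  sel <- as.integer(format(ws$date, "%m")) %in% months
  ws$rain[sel] <- ws$rain[sel] * scale_factor
  ws
}

#' Add extreme daily rain events
#'
#' For `f = events_per_month` events in a month of `L` days, event days are
#' `round(L * k / (f + 1))` for `k = 1..f` (deterministic, evenly spaced);
#' `event_depth` mm is added to any rain already falling on those days.
#'
#' @param ws a [weather_series()].
#' @param event_depth depth added per event (mm).
#' @param events_per_month integer 0-4.
#' @param months integer months (1-12) receiving events.
#' @return The perturbed [weather_series()].
#' @export
inject_extreme_events <- function(ws, event_depth, events_per_month, months) {
  stopifnot(event_depth >= 0, events_per_month %in% 0:4)
  ws <- validate_weather(ws)
  if (events_per_month == 0L || !length(months)) return(ws)
  mon <- as.integer(format(ws$date, "%m"))
  dom <- as.integer(format(ws$date, "%d"))
  ym <- format(ws$date, "%Y-%m")
  for (g in unique(ym[mon %in% months])) {
    idx <- which(ym == g)
    L <- length(idx)
    ev <- unique(pmax(1L, pmin(L, round(L * seq_len(events_per_month) /
                                          (events_per_month + 1)))))
    ws$rain[idx[ev]] <- ws$rain[idx[ev]] + event_depth
  }
  ws
}

#' Apply a climate scenario to a weather series
#'
#' @param ws a [weather_series()].
#' @param scn a [climate_scenario()].
#' @return The perturbed [weather_series()]; `kind = "none"` returns `ws`
#'   unchanged.
#' @export
apply_scenario <- function(ws, scn) {
  stopifnot(inherits(scn, "climate_scenario"))
  switch(scn$kind,
    none = validate_weather(ws),
    monthly_scale = apply_monthly_rain_increase(ws, scn$months,
                                                scn$scale_factor),
    extreme_events = inject_extreme_events(ws, scn$event_depth,
                                           scn$events_per_month, scn$months))
}

#' The eight built-in rainfall risk scenarios
#'
#' Three single-month +25% scenarios (June, July, August), one three-month
#' +25% scenario, and four extreme-event scenarios adding 50 mm events one to
#' four times per month in June-August.
#'
#' @return A list of eight [climate_scenario()] objects.
#' @export
risk_scenarios <- function() {
  c(lapply(6:8, function(m)
      climate_scenario("monthly_scale", months = m, scale_factor = 1.25,
                       name = paste0("+25% ", month.abb[m]))),
    list(climate_scenario("monthly_scale", months = 6:8, scale_factor = 1.25,
                          name = "+25% Jun-Aug")),
    lapply(1:4, function(f)
      climate_scenario("extreme_events", months = 6:8, event_depth = 50,
                       events_per_month = f,
                       name = paste0(f, "x50mm/month"))))
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
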