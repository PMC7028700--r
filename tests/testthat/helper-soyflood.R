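# Shared fixtures for the test suite. Deterministic weather removes
# sampling jitter so mechanism-level properties can be asserted tightly.

det_weather <- function(year = 1995, rain_every = 3, rain_mm = 10,
                        tmean_annual = 17.5, tamp = 10.5, trange = 9.5,
                        radn_mean = 16, radn_amp = 7.5) {
  dates <- seq(as.Date(paste0(year, "-01-01")),
               as.Date(paste0(year, "-12-31")), by = "day")
  doy <- seq_along(dates)
  tmean <- tmean_annual + tamp * cos(2 * pi * (doy - 200) / 365.25)
  radn <- pmax(1, radn_mean + radn_amp * cos(2 * pi * (doy - 172) / 365.25))
  rain <- ifelse(doy %% rain_every == 0, rain_mm, 0)
  weather_series(dates, tmean + trange / 2, tmean - trange / 2, radn, rain)
}

det_config <- function(fx = clay_fixture(), ...) {
  sim_config(det_weather(), fx$profile, fx$cultivar, sowing_doy = "05-10",
             init_mineral_n = 100, mineralization_rate = 0.9, ...)
}

# small uniform profile for unit arithmetic
flat_profile <- function(n = 4, thickness = 300, ll15 = 0.15, dul = 0.30,
                         sat = 0.40, ks = 20, kl = 0.08)
  soil_profile(rep(thickness, n), ll15, dul, sat, 1.3, ks, kl)
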