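#' @export
print.season_result <- function(x, ...) {
  cat("Soybean season", if (x$oxdef_enabled) "(waterlogging functions on)"
      else "(original model)", "\n")
  cat(sprintf("  yield        %8.0f kg/ha\n", x$yield))
  cat(sprintf("  biomass      %8.0f kg/ha\n", x$biomass))
  cat(sprintf("  N fixed      %8.1f kg/ha (%.0f%% of plant N)\n",
              x$cum_fixed_n,
              100 * x$cum_fixed_n / max(1e-9, x$cum_fixed_n +
                                          x$cum_uptake_n)))
  cat(sprintf("  N uptake     %8.1f kg/ha\n", x$cum_uptake_n))
  cat(sprintf("  maturity     %s%s\n", format(x$maturity_date),
              if (x$truncated) " (truncated)" else ""))
  cat(sprintf("  max roots    %8.0f mm\n", x$max_root_depth))
  invisible(x)
}

#' @export
summary.season_result <- function(object, ...) {
  tr <- object$trace
  fl <- sum(tr$flood_forced)
  wl <- sum(tr$frac_submerged > 0)
  out <- list(
    yield = object$yield, biomass = object$biomass,
    harvest_index = object$yield / max(1e-9, object$biomass),
    fixed_n = object$cum_fixed_n, uptake_n = object$cum_uptake_n,
    fixation_share = object$cum_fixed_n /
      max(1e-9, object$cum_fixed_n + object$cum_uptake_n),
    season_days = nrow(tr), forced_flood_days = fl, waterlogged_days = wl,
    min_photo_multiplier = min(tr$photo), min_fix_multiplier = min(tr$fix),
    water_balance = object$water_balance)
  class(out) <- "summary.season_result"
  out
}

#' @export
print.summary.season_result <- function(x, ...) {
  cat(sprintf("yield %0.f kg/ha, biomass %0.f kg/ha (HI %.2f)\n",
              x$yield, x$biomass, x$harvest_index))
  cat(sprintf("N: fixed %.1f + uptake %.1f kg/ha (fixation share %.0f%%)\n",
              x$fixed_n, x$uptake_n, 100 * x$fixation_share))
  cat(sprintf("%d season days: %d flood-forced, %d waterlogged\n",
              x$season_days, x$forced_flood_days, x$waterlogged_days))
  cat(sprintf("worst multipliers: photosynthesis %.2f, fixation %.2f\n",
              x$min_photo_multiplier, x$min_fix_multiplier))
  cat(sprintf("water balance closure: %.2e mm\n", x$water_balance$closure))
  invisible(x)
}

#' Plot a simulated season
#'
#' Four panels against time: biomass and grain, leaf area index, water-table
#' depth, and the daily stress multipliers.
#'
#' @param x a [run_season()] result.
#' @param ... unused.
#' @export
plot.season_result <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 2), mar = c(3.5, 4, 1.5, 1),
                      mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  graphics::plot(tr$date, tr$biomass, type = "l", xlab = "", lwd = 2,
                 ylab = "kg/ha", main = "biomass and grain")
  graphics::lines(tr$date, tr$grain, lty = 2, lwd = 2)
  graphics::plot(tr$date, tr$lai, type = "l", xlab = "", ylab = "LAI",
                 lwd = 2, main = "leaf area index")
  graphics::plot(tr$date, -tr$water_table, type = "l", xlab = "",
                 ylab = "water table (mm)", lwd = 2, main = "water table")
  graphics::plot(tr$date, tr$photo, type = "l", ylim = c(0, 1), xlab = "",
                 ylab = "multiplier", lwd = 2, main = "stress multipliers")
  graphics::lines(tr$date, tr$fix, col = 2, lwd = 2)
  graphics::lines(tr$date, tr$drought, col = 4, lty = 3)
  graphics::legend("bottomleft", c("photo", "fixation", "drought"),
                   col = c(1, 2, 4), lty = c(1, 1, 3), bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
print.flood_experiment <- function(x, ...) {
  cat("Flood experiment (", sum(x$stage != "control"), " treatments + control)\n",
      sep = "")
  print.data.frame(cbind(x[c("stage", "duration_days")],
                         yield = round(x$yield),
                         penalty_pct = round(x$penalty_pct, 1)),
                   row.names = FALSE)
  invisible(x)
}

#' @export
print.risk_summary <- function(x, ...) {
  cat("Rainfall-scenario risk analysis (", x$n_years[1L], " years)\n",
      sep = "")
  print.data.frame(data.frame(scenario = x$scenario,
                              mean_penalty = round(x$mean_penalty_pct, 1),
                              sd = round(x$sd_penalty_pct, 1)),
                   row.names = FALSE)
  invisible(x)
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat("Waterlogging-function sensitivity (% change vs default)\n")
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.fixture_set <- function(x, ...) {
  cat("fixture_set '", x$name, "': ", length(x$profile$thickness),
      "-layer profile, MG ", x$cultivar$maturity_group,
      ", sowing ", x$sowing_doy, "\n", sep = "")
  invisible(x)
}
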