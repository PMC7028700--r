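#' Goodness-of-fit and penalty metrics
#'
#' Standard calibration-style metrics over paired observed/simulated series:
#' relative root mean square error (RRMSE, percent of the observed mean),
#' modelling efficiency (Nash-Sutcliffe form) and squared Pearson
#' correlation, plus the control-normalisation and percent-yield-penalty
#' helpers used in treatment comparisons.
#'
#' @param observed,simulated numeric vectors of equal length (>= 2).
#' @return `rrmse()`: RRMSE in percent.
#' @name metrics
NULL

check_pairs <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 2)
    stop("observed and simulated must have equal length >= 2")
  if (anyNA(observed) || anyNA(simulated)) stop("missing values in series")
}

#' @rdname metrics
#' @export
rrmse <- function(observed, simulated) {
  check_pairs(observed, simulated)
  if (mean(observed) == 0) stop("RRMSE undefined: mean(observed) is 0")
  100 * sqrt(mean((simulated - observed)^2)) / mean(observed)
}

#' @rdname metrics
#' @return `modelling_efficiency()`: dimensionless, 1 for a perfect fit, 0
#'   for a fit no better than the observed mean, negative when worse.
#' @export
modelling_efficiency <- function(observed, simulated) {
  check_pairs(observed, simulated)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("modelling efficiency undefined: observed has no variance")
  1 - sum((simulated - observed)^2) / sst
}

#' @rdname metrics
#' @return `r_squared()`: squared Pearson correlation in [0, 1].
#' @export
r_squared <- function(observed, simulated) {
  check_pairs(observed, simulated)
  if (stats::sd(observed) == 0 || stats::sd(simulated) == 0)
    stop("r-squared undefined for a constant series")
  stats::cor(observed, simulated)^2
}

#' @rdname metrics
#' @param values numeric vector to normalise.
#' @param control_value positive control value.
#' @return `normalize_to_control()`: `values / control_value`.
#' @export
normalize_to_control <- function(values, control_value) {
  if (control_value <= 0) stop("control value must be positive")
  values / control_value
}

#' @rdname metrics
#' @param treated,control yields (control > 0).
#' @return `yield_penalty_percent()`: `100 * (control - treated)/control`.
#' @export
yield_penalty_percent <- function(treated, control) {
  if (any(control <= 0)) stop("control yield must be positive")
  100 * (control - treated) / control
}
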