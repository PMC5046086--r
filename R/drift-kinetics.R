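# The micro-modified pH-drift calcification assay.
#
# Chemistry: Ca2+ + HCO3- -> CaCO3 + H+. In an unbuffered well the proton
# release acidifies the solution, so the pH drop (read via thymol blue
# absorbance at 594 nm) proxies CaCO3 production. Analysis works on
# [H+] = 10^(-pH) rather than pH to remove the logarithmic compression of
# the pH scale.

#' Default analysis configuration for the drift assay
#'
#' @param threshold_frac Fraction of the total \[H+\] increase defining the
#'   nucleation threshold (default 0.10).
#' @param window Fractional \[H+\]-increase band over which the
#'   calcification rate is regressed (default 20--60\%).
#' @param baseline_points Number of initial readings whose median is the
#'   \[H+\] baseline (default 10).
#' @param smooth_points Rolling-median window (readings) used to smooth the
#'   \[H+\] series before peak/threshold detection (default 5).
#' @param min_delta_h_mad Minimum total \[H+\] increase, in multiples of the
#'   baseline median absolute deviation, below which a well is flagged
#'   \code{no_precipitation} (default 3).
#' @param indicator_range pH span over which the indicator dye responds
#'   reliably; pH values outside it are flagged, not clipped.
#' @param crossing_on Detect the threshold crossing on the
#'   \code{"smoothed"} (default) or \code{"raw"} \[H+\] series.
#' @return Named list of settings.
#' @export
drift_config <- function(threshold_frac = 0.10, window = c(0.20, 0.60),
                         baseline_points = 10L, smooth_points = 5L,
                         min_delta_h_mad = 3, indicator_range = c(7.6, 9.0),
                         crossing_on = c("smoothed", "raw")) {
  stopifnot(threshold_frac > 0, threshold_frac < 1,
            length(window) == 2L, window[1] < window[2],
            baseline_points >= 1, smooth_points >= 1, min_delta_h_mad >= 0)
  list(threshold_frac = threshold_frac, window = window,
       baseline_points = as.integer(baseline_points),
       smooth_points = as.integer(smooth_points),
       min_delta_h_mad = min_delta_h_mad,
       indicator_range = indicator_range,
       crossing_on = match.arg(crossing_on))
}

#' Fit the pH standard curve
#'
#' Each standard well's 594 nm absorbance is averaged over the full time
#' course ("throughout the assay"), replicate wells of the same pH are
#' averaged, and a first-order polynomial (ordinary least squares of mean
#' absorbance on pH) gives the calibration.
#'
#' @param ph_values Numeric vector, one pH per standard well.
#' @param series_list List of absorbance series aligned with
#'   \code{ph_values}; each element either a numeric vector of A594
#'   readings or a data.frame with an \code{a594} column.
#' @param slope_tol Minimum |slope| regarded as invertible.
#' @return Object of class \code{standard_curve}: slope (absorbance per pH
#'   unit), intercept, r_squared, n_standards, ph_range.
#' @export
fit_standard_curve <- function(ph_values, series_list, slope_tol = 1e-12) {
  if (length(ph_values) != length(series_list))
    stopf("one absorbance series per standard pH required")
  if (length(unique(ph_values)) < 2L)
    stopf("need >= 2 distinct standard pH values")
  well_mean <- vapply(series_list, function(s) {
    v <- if (is.data.frame(s)) s$a594 else as.numeric(s)
    mean(v)
  }, 0)
  # replicate wells of one pH averaged before the fit
  mean_by_ph <- tapply(well_mean, ph_values, mean)
  ph <- as.numeric(names(mean_by_ph))
  ab <- as.numeric(mean_by_ph)
  co <- ols_fit(ph, ab)
  if (abs(co["slope"]) < slope_tol)
    stopf("standard-curve slope indistinguishable from 0")
  resid <- ab - (co["intercept"] + co["slope"] * ph)
  sst <- sum((ab - mean(ab))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(resid^2) / sst
  structure(list(slope = unname(co["slope"]),
                 intercept = unname(co["intercept"]),
                 r_squared = r2, n_standards = length(ph),
                 ph_range = range(ph)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("pH standard curve: A594 = %.4g + %.4g * pH (r^2 = %.4f, %d levels, pH %.1f-%.1f)\n",
              x$intercept, x$slope, x$r_squared, x$n_standards,
              x$ph_range[1], x$ph_range[2]))
  invisible(x)
}

#' Convert absorbance to pH via a standard curve
#'
#' @param a594 Numeric absorbance values.
#' @param curve A \code{standard_curve}.
#' @param indicator_range pH span of reliable indicator response; values
#'   outside it are flagged (attribute \code{outside_indicator_range}), not
#'   clipped.
#' @return Numeric pH values with a logical attribute
#'   \code{outside_indicator_range}.
#' @export
absorbance_to_ph <- function(a594, curve, indicator_range = c(7.6, 9.0)) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stopf("zero-slope curve is not invertible")
  ph <- (a594 - curve$intercept) / curve$slope
  attr(ph, "outside_indicator_range") <-
    ph < indicator_range[1] | ph > indicator_range[2]
  ph
}

#' Convert pH to proton concentration
#'
#' \code{[H+] = 10^(-pH)} (mol/L). A formal re-scaling — no activity
#' correction is applied.
#'
#' @param ph Numeric pH values (finite).
#' @return Proton concentrations, mol/L.
#' @export
ph_to_hplus <- function(ph) {
  if (any(!is.finite(ph))) stopf("non-finite pH value")
  10^(-as.numeric(ph))
}

# Shared per-well kinetics: baseline, smoothing, total increase, threshold
# crossing, rate window. times in seconds, h in mol/L.
kinetics_core <- function(time_s, hplus, config = drift_config()) {
  n <- length(hplus)
  if (n < config$smooth_points) stopf("series shorter than smoothing window")
  k <- min(config$baseline_points, n)
  baseline <- stats::median(hplus[seq_len(k)])
  base_mad <- stats::mad(hplus[seq_len(k)])
  smoothed <- roll_median(hplus, config$smooth_points)
  peak <- max(smoothed)
  delta_h <- peak - baseline
  min_delta <- config$min_delta_h_mad * base_mad
  defined <- delta_h > min_delta && delta_h > 0
  t_h <- time_s / 3600
  out <- list(baseline = baseline, delta_h = max(delta_h, 0),
              defined = defined, flags = character(0))
  if (!defined) {
    out$flags <- "no_precipitation"
    out$nucleation_h <- NA_real_
    out$rate <- NA_real_
    return(out)
  }
  y_cross <- if (config$crossing_on == "smoothed") smoothed else hplus
  out$nucleation_h <- first_crossing(
    t_h, y_cross, baseline + config$threshold_frac * delta_h)
  lo <- baseline + config$window[1] * delta_h
  hi <- baseline + config$window[2] * delta_h
  # membership decided on the smoothed series; fit on raw values there
  sel <- smoothed >= lo & smoothed <= hi
  if (sum(sel) < 2L || length(unique(t_h[sel])) < 2L) {
    out$rate <- NA_real_
    out$flags <- c(out$flags, "rate_window_empty")
  } else {
    out$rate <- unname(ols_fit(t_h[sel], hplus[sel])["slope"])
  }
  out
}

#' Nucleation time of a \[H+\] time series
#'
#' The lag before detectable precipitation: the first time the proton
#' concentration has risen by \code{threshold_frac} (default 10\%) of the
#' total increase observed over the assay. The baseline is the median of
#' the first \code{baseline_points} readings, the peak the maximum of a
#' rolling-median-smoothed series, and the crossing is linearly
#' interpolated between samples.
#'
#' @param time_s Times in seconds, strictly increasing.
#' @param hplus Proton concentrations, mol/L.
#' @param config See [drift_config()]; \code{threshold_frac} lives there.
#' @return Nucleation time in hours, or \code{NA} with attribute
#'   \code{flags} containing \code{"no_precipitation"} when the total
#'   increase is below the noise floor.
#' @export
nucleation_time <- function(time_s, hplus, config = drift_config()) {
  core <- kinetics_core(time_s, hplus, config)
  structure(core$nucleation_h, flags = core$flags)
}

#' Calcification rate of a \[H+\] time series
#'
#' OLS slope of \[H+\] against time over the readings whose smoothed value
#' lies between 20\% and 60\% (configurable) of the total \[H+\] increase.
#'
#' @inheritParams nucleation_time
#' @return Rate in mol/L per hour, or \code{NA} (flagged) when undefined.
#' @export
calcification_rate <- function(time_s, hplus, config = drift_config()) {
  core <- kinetics_core(time_s, hplus, config)
  structure(core$rate, flags = core$flags)
}

#' Normalize kinetics to the no-protein controls
#'
#' Each well's nucleation time and calcification rate is divided by the
#' mean of the defined control values on the same plate, which removes
#' plate-to-plate systematic shifts.
#'
#' @param records data.frame with columns \code{role}, \code{nucleation_h},
#'   \code{rate}.
#' @return The records with \code{norm_nucleation} and \code{norm_rate}
#'   columns added.
#' @export
normalize_to_controls <- function(records) {
  ctrl <- records$role == "control"
  if (!any(ctrl)) stopf("no control wells to normalize against")
  norm_one <- function(values) {
    m <- mean(values[ctrl], na.rm = TRUE)
    if (!is.finite(m) || m == 0)
      stopf("control mean undefined or zero; cannot normalize")
    values / m
  }
  records$norm_nucleation <- norm_one(records$nucleation_h)
  records$norm_rate <- norm_one(records$rate)
  records
}

#' Fit the pH-drift calcification assay to a plate dataset
#'
#' The full analysis in one call: fits the pH standard curve from the
#' standard wells, converts each sample/control well's absorbance to pH and
#' then to \[H+\], extracts per-well nucleation times and calcification
#' rates, and normalizes both to the no-protein controls.
#'
#' @param plate A \code{plate_dataset} from [read_plate()],
#'   [plate_dataset()] or [simulate_drift_plate()].
#' @param config Analysis settings from [drift_config()].
#' @return An object of class \code{drift_fit} with components
#'   \code{curve} (the \code{standard_curve}), \code{records} (one row per
#'   analysed well: dose, baseline, total increase, raw and normalized
#'   metrics, QC flags) and \code{traces} (per-well \[H+\] series, for
#'   [plot.drift_fit()]).
#' @seealso [dose_response_tests()] for the downstream statistics.
#' @export
drift_fit <- function(plate, config = drift_config()) {
  stopifnot(inherits(plate, "plate_dataset"))
  layout <- plate$layout
  series_by_well <- split(plate$series, plate$series$well)

  std <- layout[layout$role == "standard" & layout$well %in% names(series_by_well), ]
  if (nrow(std) < 2L) stopf("need >= 2 standard wells with readings")
  curve <- fit_standard_curve(std$ph_value, series_by_well[std$well])

  wells <- layout[layout$role %in% c("sample", "control") &
                    layout$well %in% names(series_by_well), ]
  traces <- list()
  rows <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    w <- wells$well[i]
    s <- series_by_well[[w]]
    ph <- absorbance_to_ph(s$a594, curve, config$indicator_range)
    flags <- character(0)
    if (any(attr(ph, "outside_indicator_range")))
      flags <- "outside_indicator_range"
    h <- ph_to_hplus(as.numeric(ph))
    core <- kinetics_core(s$time_s, h, config)
    traces[[w]] <- data.frame(time_s = s$time_s, hplus = h)
    rows[[i]] <- data.frame(
      well = w, sample_id = wells$sample_id[i], role = wells$role[i],
      dose = wells$dose[i], baseline_h = core$baseline,
      total_increase = core$delta_h, nucleation_h = core$nucleation_h,
      rate = core$rate,
      qc_flags = paste(c(flags, core$flags), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rows)
  records <- normalize_to_controls(records)
  structure(list(curve = curve, records = records, traces = traces,
                 config = config),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat("pH-drift calcification assay fit\n")
  print(x$curve)
  n_def <- sum(!is.na(x$records$nucleation_h))
  cat(sprintf("%d wells analysed (%d with detectable precipitation)\n",
              nrow(x$records), n_def))
  invisible(x)
}

#' @export
coef.drift_fit <- function(object, ...) {
  c(intercept = object$curve$intercept, slope = object$curve$slope)
}

#' Summarize a drift-assay fit by dose group
#'
#' @param object A \code{drift_fit}.
#' @param ... Unused.
#' @return data.frame with per-dose n, mean and SEM of the normalized
#'   nucleation time and calcification rate, classed
#'   \code{summary.drift_fit}.
#' @export
summary.drift_fit <- function(object, ...) {
  rec <- object$records
  grp <- split(rec, rec$dose)
  sem <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }
  out <- do.call(rbind, lapply(grp, function(g) data.frame(
    dose = g$dose[1],
    n = sum(!is.na(g$norm_nucleation)),
    mean_norm_nucleation = mean(g$norm_nucleation, na.rm = TRUE),
    sem_norm_nucleation = sem(g$norm_nucleation),
    mean_norm_rate = mean(g$norm_rate, na.rm = TRUE),
    sem_norm_rate = sem(g$norm_rate)
  )))
  rownames(out) <- NULL
  out <- out[order(out$dose), , drop = FALSE]
  class(out) <- c("summary.drift_fit", class(out))
  out
}

#' @export
print.summary.drift_fit <- function(x, ...) {
  cat("Normalized kinetics by dose (ug/ml):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot \[H+\] trajectories of a drift-assay fit
#'
#' @param x A \code{drift_fit}.
#' @param wells Wells to draw (default: all analysed wells).
#' @param ... Passed to \code{matplot}.
#' @export
plot.drift_fit <- function(x, wells = names(x$traces), ...) {
  tr <- x$traces[wells]
  times <- tr[[1]]$time_s / 3600
  ymat <- sapply(tr, function(d) d$hplus)
  graphics::matplot(times, ymat, type = "l", lty = 1,
                    xlab = "time (h)", ylab = "[H+] (mol/L)", ...)
  invisible(x)
}

#' Per-well results of a drift-assay fit
#'
#' @param object A \code{drift_fit}.
#' @param ... Unused.
#' @return The per-well records data.frame.
#' @export
fitted.drift_fit <- function(object, ...) object$records
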