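# pH-stat validation assay: pH is held constant by NaOH titration, so the
# cumulative base-addition curve proxies cumulative CaCO3 formed.

#' Kinetics from a pH-stat cumulative base-addition curve
#'
#' Mirrors the drift-assay definitions on the titration record: the
#' nucleation time is the (interpolated) first time the cumulative base
#' added crosses \code{threshold_frac} of the total added over the run, and
#' the calcification rate is the maximum over sliding-window OLS slopes of
#' cumulative base versus time — a \emph{max} rate, because pH-stat events
#' run to completion within minutes and the instantaneous peak is the
#' informative summary.
#'
#' @param titration data.frame(time_s, base_ul) with strictly increasing
#'   times and non-decreasing cumulative base (any consistent volume or
#'   molar unit).
#' @param threshold_frac Fraction of total base defining nucleation
#'   (default 0.10).
#' @param rate_window Sliding-window length in minutes (default 2).
#' @return List of class \code{phstat_record}: \code{nucleation_min},
#'   \code{max_rate} (base units per minute), \code{total_base},
#'   \code{qc_flags}.
#' @export
phstat_metrics <- function(titration, threshold_frac = 0.10,
                           rate_window = 2) {
  titration <- validate_titration(titration)
  stopifnot(threshold_frac > 0, threshold_frac < 1, rate_window > 0)
  t_min <- titration$time_s / 60
  base <- titration$base_ul - titration$base_ul[1]
  total <- base[length(base)]
  if (total <= 0) {
    return(structure(list(nucleation_min = NA_real_, max_rate = NA_real_,
                          total_base = 0, qc_flags = "no_precipitation"),
                     class = "phstat_record"))
  }
  nuc <- first_crossing(t_min, base, threshold_frac * total)
  max_rate <- -Inf
  n <- length(t_min)
  for (i in seq_len(n - 1L)) {
    j <- which(t_min <= t_min[i] + rate_window)
    j <- j[j >= i]
    if (length(j) < 2L) next
    sl <- ols_fit(t_min[j], base[j])["slope"]
    if (sl > max_rate) max_rate <- sl
  }
  if (!is.finite(max_rate)) max_rate <- NA_real_
  structure(list(nucleation_min = nuc, max_rate = unname(max_rate),
                 total_base = total, qc_flags = character(0)),
            class = "phstat_record")
}

#' @export
print.phstat_record <- function(x, ...) {
  if (length(x$qc_flags) && "no_precipitation" %in% x$qc_flags) {
    cat("pH-stat record: no precipitation detected\n")
  } else {
    cat(sprintf("pH-stat record: nucleation %.3g min, max rate %.3g /min, total base %.3g\n",
                x$nucleation_min, x$max_rate, x$total_base))
  }
  invisible(x)
}

#' Normalize pH-stat metrics to no-protein controls
#'
#' Identical in form to the drift-assay normalization: division by the mean
#' of the defined control values.
#'
#' @param records data.frame with columns \code{role},
#'   \code{nucleation_min}, \code{max_rate}.
#' @return Records with \code{norm_nucleation} and \code{norm_rate} added.
#' @export
normalize_phstat <- function(records) {
  ctrl <- records$role == "control"
  if (!any(ctrl)) stopf("no control runs to normalize against")
  norm_one <- function(values) {
    m <- mean(values[ctrl], na.rm = TRUE)
    if (!is.finite(m) || m == 0) stopf("control mean undefined or zero")
    values / m
  }
  records$norm_nucleation <- norm_one(records$nucleation_min)
  records$norm_rate <- norm_one(records$max_rate)
  records
}
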