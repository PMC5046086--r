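# Phenomenological drift-plate simulator: logistic [H+] curves with planted
# nucleation times and rates, read out through a known standard curve.
# Exact planted truth makes this tier the one used for parameter-recovery
# checks; the mechanistic tier (sim-chem.R) supplies realism.

#' The canonical plate-reader sampling schedule
#'
#' One reading every 30 s for the first 30 min, then one every 5 min for
#' the remaining 19.5 h (20 h total; 295 readings).
#'
#' @return Numeric vector of read times in seconds.
#' @export
assay_schedule <- function() {
  c(seq(0, 1800, by = 30), seq(2100, 72000, by = 300))
}

#' Lay out a simulated drift plate with planted kinetics
#'
#' Builds the canonical plate plan: one well per pH standard level
#' (7.6--9.0 by 0.2) followed by \code{replicates} wells per dose, with the
#' planted per-well truth (nucleation time, max rate, total \[H+\]
#' increase, starting pH) attached. Dose 0 wells are the no-protein
#' controls.
#'
#' @param doses Protein doses in ug/ml (0 = control), one group each.
#' @param replicates Wells per dose.
#' @param nucleation_h True nucleation times in hours, recycled across
#'   doses.
#' @param rate True maximum rates (mol/L/h), recycled across doses.
#' @param delta_h Total \[H+\] increase per well, mol/L.
#' @param baseline_ph Starting pH.
#' @return data.frame plan consumed by [simulate_drift_plate()].
#' @export
drift_plan <- function(doses = 0, replicates = 6,
                       nucleation_h = 4, rate = 1e-8,
                       delta_h = 2e-8, baseline_ph = 8.3) {
  all_wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  ph_std <- standard_ph_series()
  n_sample <- length(doses) * replicates
  if (length(ph_std) + n_sample > length(all_wells))
    stopf("plan does not fit on a 96-well plate")
  nucleation_h <- rep_len(nucleation_h, length(doses))
  rate <- rep_len(rate, length(doses))
  std <- data.frame(
    well = all_wells[seq_along(ph_std)], role = "standard",
    ph_value = ph_std, sample_id = sprintf("std_%.1f", ph_std), dose = NA_real_,
    nucleation_h = NA_real_, rate = NA_real_, delta_h = NA_real_,
    baseline_ph = NA_real_, stringsAsFactors = FALSE
  )
  idx <- rep(seq_along(doses), each = replicates)
  smp <- data.frame(
    well = all_wells[length(ph_std) + seq_len(n_sample)],
    role = ifelse(doses[idx] == 0, "control", "sample"),
    ph_value = NA_real_,
    sample_id = sprintf("dose_%g_r%d", doses[idx],
                        sequence(rep(replicates, length(doses)))),
    dose = doses[idx],
    nucleation_h = nucleation_h[idx], rate = rate[idx],
    delta_h = delta_h, baseline_ph = baseline_ph,
    stringsAsFactors = FALSE
  )
  rbind(std, smp)
}

#' Simulate a drift-assay plate from a planted plan
#'
#' Sample and control wells follow a logistic proton course
#' \code{H(t) = H0 + dH / (1 + exp(-(t - t50)/s))} with
#' \code{s = dH / (4 * rate)} and \code{t50} placed so that the 10\%
#' crossing of the noiseless curve equals the planted nucleation time.
#' pH is \code{-log10(H)}; absorbance is
#' \code{intercept + slope * pH + N(0, noise_sd)}. Standard wells hold
#' their pH flat with the same absorbance noise. Deterministic given
#' \code{seed}.
#'
#' @param plan A plan from [drift_plan()] (or any data.frame with the same
#'   columns).
#' @param curve_slope,curve_intercept True standard-curve parameters
#'   (absorbance per pH unit; absorbance).
#' @param noise_sd Gaussian absorbance noise SD (instrument-level noise
#'   lives on the absorbance channel, not on pH).
#' @param sampling Read times in seconds (default [assay_schedule()]).
#' @param threshold_frac Threshold fraction the planted nucleation time
#'   refers to (default 0.10).
#' @param seed Optional RNG seed.
#' @return A \code{plate_dataset} with the plan attached as
#'   \code{attr(, "truth")}.
#' @export
simulate_drift_plate <- function(plan, curve_slope = 0.5,
                                 curve_intercept = -3.3, noise_sd = 0,
                                 sampling = assay_schedule(),
                                 threshold_frac = 0.10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.unsorted(sampling, strictly = TRUE))
    stopf("sampling times must be strictly increasing")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  t_h <- sampling / 3600
  series <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    if (plan$role[i] == "standard") {
      ph <- rep(plan$ph_value[i], length(sampling))
    } else {
      dh <- plan$delta_h[i]
      if (dh <= 0) stopf("delta_h must be positive")
      h0 <- 10^(-plan$baseline_ph[i])
      if (is.finite(plan$rate[i]) && plan$rate[i] > 0) {
        s <- dh / (4 * plan$rate[i])
        t50 <- plan$nucleation_h[i] +
          s * log((1 - threshold_frac) / threshold_frac)
        h <- h0 + dh / (1 + exp(-(t_h - t50) / s))
      } else {
        h <- rep(h0, length(sampling))  # flat well: no precipitation
      }
      ph <- -log10(h)
      if (any(ph < 0 | ph > 14)) stopf("parameters imply pH outside [0, 14]")
    }
    a <- curve_intercept + curve_slope * ph
    if (noise_sd > 0) a <- a + stats::rnorm(length(a), 0, noise_sd)
    series[[i]] <- data.frame(time_s = sampling, well = plan$well[i], a594 = a)
  }
  layout <- plan[c("well", "role", "ph_value", "sample_id", "dose")]
  ds <- plate_dataset(layout, do.call(rbind, series),
                      require_control = any(plan$role == "control"))
  attr(ds, "truth") <- plan
  attr(ds, "curve_truth") <- c(slope = curve_slope,
                               intercept = curve_intercept)
  ds
}

#' Simulate a pH-stat cumulative base-addition curve
#'
#' Logistic cumulative addition with planted nucleation time (the 10\%
#' crossing) and maximum addition rate.
#'
#' @param total_base Total base added over the run (ul or umol).
#' @param nucleation_min Planted nucleation time, minutes.
#' @param max_rate Planted maximum addition rate, base units per minute.
#' @param duration_min Recording span, minutes.
#' @param dt_s Sampling interval, seconds.
#' @param noise_sd Gaussian noise SD on the cumulative record (monotonicity
#'   restored by a running maximum).
#' @param threshold_frac Fraction the planted nucleation refers to.
#' @param seed Optional RNG seed.
#' @return data.frame(time_s, base_ul) with the planted values attached as
#'   \code{attr(, "truth")}.
#' @export
simulate_phstat <- function(total_base = 100, nucleation_min = 7,
                            max_rate = 10, duration_min = 40, dt_s = 5,
                            noise_sd = 0, threshold_frac = 0.10,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_min <- seq(0, duration_min, by = dt_s / 60)
  s <- total_base / (4 * max_rate)
  t50 <- nucleation_min + s * log((1 - threshold_frac) / threshold_frac)
  v <- total_base / (1 + exp(-(t_min - t50) / s))
  v <- v - v[1]  # cumulative record starts at zero
  if (noise_sd > 0) v <- cummax(pmax(v + stats::rnorm(length(v), 0, noise_sd), 0))
  out <- data.frame(time_s = t_min * 60, base_ul = v)
  attr(out, "truth") <- list(total_base = total_base,
                             nucleation_min = nucleation_min,
                             max_rate = max_rate)
  out
}
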