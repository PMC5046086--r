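# Mechanistic carbonate-chemistry simulator. The drift assay's premise is
# Ca2+ + HCO3- -> CaCO3 + H+; this tier integrates a saturation-state rate
# law over a closed carbonate system so that dose-response curves emerge
# from chemistry rather than being planted. Concentration-based (no
# activity coefficients); freshwater equilibrium constants by default.

#' Carbonate-system equilibrium constants
#'
#' Defaults at 25 degrees C: K1 = 10^-6.35, K2 = 10^-10.33 (carbonic acid),
#' Kw = 10^-14, Ksp = 10^-8.48 (calcite). All overridable.
#'
#' @param K1,K2,Kw,Ksp Equilibrium constants (mol/L scale).
#' @return Named list of constants.
#' @export
carbonate_constants <- function(K1 = 10^-6.35, K2 = 10^-10.33,
                                Kw = 1e-14, Ksp = 10^-8.48) {
  list(K1 = K1, K2 = K2, Kw = Kw, Ksp = Ksp)
}

#' Solve carbonate-system pH from alkalinity and DIC
#'
#' Bisection on pH in \[2, 12\] of the alkalinity balance
#' \code{alk = [HCO3-] + 2[CO3^2-] + [OH-] - [H+]}, with DIC partitioned
#' among CO2*, HCO3- and CO3^2- by K1 and K2. The calcite saturation state
#' is \code{omega = [Ca][CO3] / Ksp}.
#'
#' @param ca Calcium, mol/L.
#' @param dic Dissolved inorganic carbon, mol/L (>= 0).
#' @param alkalinity Carbonate alkalinity, eq/L.
#' @param constants See [carbonate_constants()].
#' @param tol Bisection tolerance on pH.
#' @return List: ph, h, co2, hco3, co3, oh, omega.
#' @export
solve_carbonate_ph <- function(ca, dic, alkalinity,
                               constants = carbonate_constants(),
                               tol = 1e-7) {
  if (dic < 0) stopf("DIC must be >= 0")
  if (!is.finite(alkalinity)) stopf("alkalinity must be finite")
  resid <- function(ph) {
    h <- 10^(-ph)
    denom <- h^2 + constants$K1 * h + constants$K1 * constants$K2
    hco3 <- dic * constants$K1 * h / denom
    co3 <- dic * constants$K1 * constants$K2 / denom
    hco3 + 2 * co3 + constants$Kw / h - h - alkalinity
  }
  lo <- 2; hi <- 12
  if (resid(lo) > 0 || resid(hi) < 0)
    stopf("no pH root in [2, 12] for this composition")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (resid(mid) < 0) lo <- mid else hi <- mid
  }
  ph <- (lo + hi) / 2
  h <- 10^(-ph)
  denom <- h^2 + constants$K1 * h + constants$K1 * constants$K2
  co3 <- dic * constants$K1 * constants$K2 / denom
  list(ph = ph, h = h,
       co2 = dic * h^2 / denom,
       hco3 = dic * constants$K1 * h / denom,
       co3 = co3, oh = constants$Kw / h,
       omega = ca * co3 / constants$Ksp)
}

#' Initialize a chemical state for the simulator
#'
#' @param ca,dic,mg Initial concentrations, mol/L. Defaults (Ca 10 mM, DIC
#'   10 mM, Mg 50 mM) are placeholder assay-buffer values; the Mg:Ca of 5
#'   mimics the intestinal-fluid ionic milieu where Mg far exceeds Ca.
#' @param alkalinity Carbonate alkalinity, eq/L.
#' @param dose Matrix protein dose in the well, ug/ml.
#' @param constants See [carbonate_constants()].
#' @return List of class \code{chem_state}: concentrations, pH, saturation
#'   state omega, and cumulative \code{precipitated} / \code{mg_precipitated}
#'   (mol/L).
#' @export
chem_state <- function(ca = 0.010, dic = 0.010, mg = 0.050,
                       alkalinity = 0.010, dose = 0,
                       constants = carbonate_constants()) {
  if (any(c(ca, dic, mg) < 0)) stopf("concentrations must be >= 0")
  sol <- solve_carbonate_ph(ca, dic, alkalinity, constants)
  structure(list(ca = ca, dic = dic, mg = mg, alkalinity = alkalinity,
                 dose = dose, ph = sol$ph, omega = sol$omega,
                 precipitated = 0, mg_precipitated = 0,
                 constants = constants),
            class = "chem_state")
}

#' Biphasic matrix dose-response factor
#'
#' \code{f(c) = (1 + a * c / (c + K_p)) / (1 + (c / K_i)^h)}: a saturating
#' promotion term at low dose divided by a Hill-type inhibition term at
#' high dose — the synthetic stand-in for the observed biphasic effect of
#' organic matrix on CaCO3 production.
#'
#' @param dose Protein dose, ug/ml.
#' @param a Maximum fold promotion (default 2).
#' @param K_p Promotion half-saturation dose, ug/ml (default 0.1).
#' @param K_i Inhibition midpoint dose, ug/ml (default 2).
#' @param h Inhibition Hill coefficient (default 3).
#' @return Dimensionless rate multiplier.
#' @export
matrix_dose_factor <- function(dose, a = 2, K_p = 0.1, K_i = 2, h = 3) {
  (1 + a * dose / (dose + K_p)) / (1 + (dose / K_i)^h)
}

#' Dose-dependent Mg partition coefficient
#'
#' \code{D(c) = D0 / (1 + c / K_m)}: the fraction of the Mg:Ca solution
#' ratio carried into the mineral, suppressed by matrix dose (matching the
#' observed decrease of mineral Mg content at high dose). Defaults are
#' calibrated so the zero-dose mineral sits near the top of the observed
#' in vitro span.
#'
#' @param dose Protein dose, ug/ml.
#' @param D0 Zero-dose partition coefficient (default 0.11).
#' @param K_m Half-suppression dose, ug/ml (default 1).
#' @return Dimensionless partition coefficient.
#' @export
mg_partition <- function(dose, D0 = 0.11, K_m = 1) {
  D0 / (1 + dose / K_m)
}

#' Advance the chemical state by one precipitation step
#'
#' Rate law \code{r = f(c) * k_rate * max(omega - 1, 0)^n} (mol/L/h).
#' Per unit precipitated: Ca and DIC fall by 1, alkalinity by 2 (the
#' CaCO3 stoichiometry), Mg is removed at
#' \code{D(c) * (Mg/Ca) * r}, and pH is re-solved. Steps that would
#' overdraw any pool are split into sub-steps automatically.
#'
#' @param state A \code{chem_state}.
#' @param dt Time step, hours.
#' @param k_rate Rate constant, mol/L/h at omega - 1 = 1.
#' @param order Rate-law order n (default 2).
#' @param dose_factor Function giving the matrix rate multiplier from dose
#'   (default [matrix_dose_factor()]).
#' @param partition Function giving the Mg partition coefficient from dose
#'   (default [mg_partition()]).
#' @return The advanced \code{chem_state}.
#' @export
step_precipitation <- function(state, dt, k_rate = 2e-9, order = 2,
                               dose_factor = matrix_dose_factor,
                               partition = mg_partition) {
  stopifnot(inherits(state, "chem_state"), dt > 0)
  f <- dose_factor(state$dose)
  D <- partition(state$dose)
  remaining <- dt
  while (remaining > 0) {
    r <- f * k_rate * max(state$omega - 1, 0)^order
    if (r <= 0) break
    # cap each sub-step at 5% of the tightest pool
    cap <- 0.05 * min(state$ca, state$dic, state$alkalinity / 2)
    step <- min(remaining, if (cap > 0) cap / r else remaining)
    dprec <- r * step
    dmg <- D * (state$mg / state$ca) * dprec
    state$ca <- state$ca - dprec
    state$dic <- state$dic - dprec
    state$alkalinity <- state$alkalinity - 2 * dprec
    state$mg <- max(state$mg - dmg, 0)
    state$precipitated <- state$precipitated + dprec
    state$mg_precipitated <- state$mg_precipitated + dmg
    sol <- solve_carbonate_ph(state$ca, state$dic, state$alkalinity,
                              state$constants)
    state$ph <- sol$ph
    state$omega <- sol$omega
    remaining <- remaining - step
  }
  state
}

#' Mechanistic drift curve for one well
#'
#' Integrates [step_precipitation()] over the assay and reads out pH at
#' the sampling schedule.
#'
#' @param dose Matrix dose, ug/ml.
#' @param sampling Read times, seconds (default [assay_schedule()]).
#' @param k_rate,order,dose_factor,partition See [step_precipitation()].
#' @param init Initial state factory; a function of \code{dose} returning
#'   a \code{chem_state} (default [chem_state()]).
#' @return List: \code{ph} (pH at each sampling time), \code{state} (final
#'   \code{chem_state}).
#' @export
simulate_drift_mechanistic <- function(dose = 0, sampling = assay_schedule(),
                                       k_rate = 2e-9, order = 2,
                                       dose_factor = matrix_dose_factor,
                                       partition = mg_partition,
                                       init = function(dose) chem_state(dose = dose)) {
  state <- init(dose)
  t_h <- sampling / 3600
  ph <- numeric(length(t_h))
  ph[1] <- state$ph
  for (i in seq_along(t_h)[-1]) {
    state <- step_precipitation(state, t_h[i] - t_h[i - 1], k_rate = k_rate,
                                order = order, dose_factor = dose_factor,
                                partition = partition)
    ph[i] <- state$ph
  }
  list(ph = ph, state = state)
}

#' Mechanistic drift plate across doses
#'
#' Builds a \code{plate_dataset} (standards plus one well per dose per
#' replicate) whose sample absorbance comes from the mechanistic
#' simulator, ready for [drift_fit()].
#'
#' @param doses Doses in ug/ml (0 = control).
#' @param replicates Wells per dose.
#' @param curve_slope,curve_intercept True standard-curve parameters.
#' @param noise_sd Absorbance noise SD.
#' @param sampling Read times, seconds.
#' @param seed Optional RNG seed.
#' @param ... Passed to [simulate_drift_mechanistic()].
#' @return A \code{plate_dataset}; final \code{chem_state}s attached as
#'   \code{attr(, "final_states")} (named by well).
#' @export
simulate_mechanistic_plate <- function(doses = c(0, 0.1, 5), replicates = 1,
                                       curve_slope = 0.5,
                                       curve_intercept = -3.3,
                                       noise_sd = 0,
                                       sampling = assay_schedule(),
                                       seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  all_wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  ph_std <- standard_ph_series()
  series <- list()
  layout <- list()
  states <- list()
  w <- 0L
  add_well <- function(ph, role, ph_value, sample_id, dose) {
    w <<- w + 1L
    well <- all_wells[w]
    a <- curve_intercept + curve_slope * ph
    if (noise_sd > 0) a <- a + stats::rnorm(length(a), 0, noise_sd)
    series[[well]] <<- data.frame(time_s = sampling, well = well, a594 = a)
    layout[[well]] <<- data.frame(well = well, role = role,
                                  ph_value = ph_value, sample_id = sample_id,
                                  dose = dose, stringsAsFactors = FALSE)
    well
  }
  for (p in ph_std)
    add_well(rep(p, length(sampling)), "standard", p,
             sprintf("std_%.1f", p), NA_real_)
  # one mechanistic trajectory per dose; replicates differ only by noise
  for (d in doses) {
    run <- simulate_drift_mechanistic(dose = d, sampling = sampling, ...)
    for (r in seq_len(replicates)) {
      well <- add_well(run$ph, if (d == 0) "control" else "sample",
                       NA_real_, sprintf("dose_%g_r%d", d, r), d)
      states[[well]] <- run$state
    }
  }
  ds <- plate_dataset(do.call(rbind, layout), do.call(rbind, series))
  attr(ds, "final_states") <- states
  ds
}

#' Simulate EDS readings of mineral formed across a dose series
#'
#' For each dose the mechanistic simulator is run to completion and the
#' mineral's Mg mole fraction is taken from the cumulative Mg and Ca
#' precipitated; per-reading Gaussian noise on the atomic fractions mimics
#' the spot-to-spot heterogeneity of EDS quantification. The designated
#' in-vivo-like condition uses an effective dose chosen so the simulated
#' partition matches field-collected intestinal precipitates.
#'
#' @param doses In vitro doses, ug/ml.
#' @param n_samples Independent mineral samples per dose.
#' @param n_readings EDS readings per sample (conventionally 3).
#' @param noise_sd Absolute noise SD on each atomic fraction.
#' @param cation_fraction Total Mg+Ca atomic fraction in the analysed
#'   volume (sets the scale of the reported fractions).
#' @param include_invivo Add an \code{"in_vivo"}-labelled sample set.
#' @param invivo_dose Effective dose of the in-vivo-like condition, ug/ml.
#' @param duration_h Simulated precipitation time, hours.
#' @param seed Optional RNG seed.
#' @param ... Passed to [simulate_drift_mechanistic()].
#' @return EDS data.frame (see [read_eds()]) with columns sample_id, dose,
#'   reading, mg, ca.
#' @export
simulate_eds <- function(doses = c(0, 0.1, 0.5, 1, 2.5, 5), n_samples = 3,
                         n_readings = 3, noise_sd = 0.002,
                         cation_fraction = 0.2, include_invivo = TRUE,
                         invivo_dose = 0.7, duration_h = 20, seed = NULL,
                         ...) {
  if (!is.null(seed)) set.seed(seed)
  sampling <- seq(0, duration_h * 3600, by = 1800)
  one_dose <- function(d, label) {
    run <- simulate_drift_mechanistic(dose = d, sampling = sampling, ...)
    st <- run$state
    if (st$precipitated + st$mg_precipitated <= 0)
      stopf("no mineral formed at dose %g", d)
    mg_frac <- st$mg_precipitated / (st$mg_precipitated + st$precipitated)
    rows <- expand.grid(sample = seq_len(n_samples),
                        reading = seq_len(n_readings))
    mg <- pmax(mg_frac * cation_fraction +
                 stats::rnorm(nrow(rows), 0, noise_sd), 1e-6)
    ca <- pmax((1 - mg_frac) * cation_fraction +
                 stats::rnorm(nrow(rows), 0, noise_sd), 1e-6)
    data.frame(sample_id = sprintf("%s_s%d", label, rows$sample),
               dose = label, reading = rows$reading,
               mg = pmin(mg, 1), ca = pmin(ca, 1),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(doses, function(d) one_dose(d, as.character(d))))
  if (include_invivo)
    out <- rbind(out, one_dose(invivo_dose, "in_vivo"))
  rownames(out) <- NULL
  out
}
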