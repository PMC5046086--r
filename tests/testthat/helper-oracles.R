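# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: regressions go through lm() or hand formulas,
# root finding through dense grid scans, maxima through exhaustive search.

# Closed-form simple least squares (hand formulas).
ols_oracle <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# pI by dense grid scan of the Henderson-Hasselbalch charge: the pH grid
# point where the charge changes sign (step 1e-4 by default).
grid_pi_oracle <- function(sequence, pka_set = "EMBOSS",
                           include_termini = TRUE, step = 1e-4) {
  ph <- seq(0, 14, by = step)
  z <- protein_charge(sequence, ph, pka_set = pka_set,
                      include_termini = include_termini)
  if (all(z <= 0)) return(0)
  if (all(z >= 0)) return(14)
  i <- which(z <= 0)[1]
  (ph[i - 1] + ph[i]) / 2
}

# Holm-Sidak by direct formula arithmetic on a sorted copy.
holm_sidak_oracle <- function(p, m = length(p)) {
  ord <- order(p)
  adj <- numeric(length(p))
  running <- 0
  for (i in seq_along(ord)) {
    a <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, a)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Exhaustive pH-stat max-rate search: lm() slope over every window of the
# given time length.
phstat_max_rate_oracle <- function(time_s, base, window_min) {
  t_min <- time_s / 60
  best <- -Inf
  for (i in seq_along(t_min)) {
    j <- which(t_min >= t_min[i] & t_min <= t_min[i] + window_min)
    if (length(j) < 2) next
    sl <- unname(coef(lm(base[j] ~ t_min[j]))[2])
    if (sl > best) best <- sl
  }
  best
}

# Noiseless logistic [H+] curve on an arbitrary time grid (hours).
logistic_h <- function(t_h, h0, delta_h, nucleation_h, rate,
                       threshold_frac = 0.10) {
  s <- delta_h / (4 * rate)
  t50 <- nucleation_h + s * log((1 - threshold_frac) / threshold_frac)
  h0 + delta_h / (1 + exp(-(t_h - t50) / s))
}

# Carbonate pH by dense grid scan of the alkalinity balance.
grid_carbonate_ph_oracle <- function(dic, alkalinity,
                                     constants = carbonate_constants(),
                                     step = 1e-4) {
  ph <- seq(2, 12, by = step)
  h <- 10^(-ph)
  denom <- h^2 + constants$K1 * h + constants$K1 * constants$K2
  resid <- dic * constants$K1 * h / denom +
    2 * dic * constants$K1 * constants$K2 / denom +
    constants$Kw / h - h - alkalinity
  i <- which(resid >= 0)[1]
  (ph[i - 1] + ph[i]) / 2
}

# Small valid plate fixture: 8 standards + the given sample/control wells.
make_layout <- function(n_samples = 2, n_controls = 1, doses = 1) {
  ph_std <- seq(7.6, 9.0, by = 0.2)
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  n <- n_samples + n_controls
  data.frame(
    well = wells[seq_len(8 + n)],
    role = c(rep("standard", 8), rep("sample", n_samples),
             rep("control", n_controls)),
    ph_value = c(ph_std, rep(NA, n)),
    sample_id = c(sprintf("std%d", 1:8), sprintf("s%d", seq_len(n_samples)),
                  sprintf("c%d", seq_len(n_controls))),
    dose = c(rep(NA, 8), rep_len(doses, n_samples), rep(0, n_controls)),
    stringsAsFactors = FALSE
  )
}
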