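# Internal numerical helpers shared across modules.

# Centered rolling median; partial windows at the ends (Tukey endrule keeps
# the first/last values, which is what we want for threshold detection on
# short baselines).
roll_median <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  if (length(x) < k) stop("series shorter than smoothing window")
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# Closed-form simple OLS; returns c(intercept, slope). Used where lm() would
# be overkill (per-well rate windows inside tight loops).
ols_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate regressor: no variance in x")
  slope <- sum((x - mx) * (y - my)) / sxx
  c(intercept = my - slope * mx, slope = slope)
}

# First upward crossing of `threshold` by `y` over `x`, linearly
# interpolated between the bracketing samples. NA if never crossed.
first_crossing <- function(x, y, threshold) {
  above <- y >= threshold
  if (above[1]) return(x[1])
  i <- which(above)[1]
  if (is.na(i)) return(NA_real_)
  x0 <- x[i - 1]; x1 <- x[i]
  y0 <- y[i - 1]; y1 <- y[i]
  if (y1 == y0) return(x1)
  x0 + (threshold - y0) / (y1 - y0) * (x1 - x0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
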