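# Statistical treatment of the dose-response assays, implemented from
# first principles: variance-stabilizing transforms, Brown-Forsythe
# homogeneity check, one-way ANOVA, and Holm-Sidak step-down comparisons
# against the no-protein control.

#' Variance-stabilizing transforms for normalized kinetics
#'
#' Control-normalized nucleation times are log transformed; normalized
#' calcification rates get a constant of 1.0 added before the log. Both
#' transforms map the control value (1 for nucleation, 0-centred rates
#' keep their scale) onto a homoscedastic axis ahead of ANOVA.
#'
#' @param nucleation Normalized nucleation times (> 0).
#' @param rate Normalized calcification rates.
#' @return List with \code{log_nucleation} = ln(nucleation) and
#'   \code{log_rate} = ln(rate + 1).
#' @export
kinetics_transforms <- function(nucleation = NULL, rate = NULL) {
  out <- list()
  if (!is.null(nucleation)) {
    if (any(nucleation <= 0, na.rm = TRUE))
      stopf("nucleation times must be positive before log transform")
    out$log_nucleation <- log(nucleation)
  }
  if (!is.null(rate)) out$log_rate <- log(rate + 1.0)
  out
}

# Sums-of-squares one-way ANOVA core; groups is a list of numeric vectors.
anova_core <- function(groups) {
  k <- length(groups)
  if (k < 2L) stopf("need >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 1L)) stopf("empty group")
  N <- sum(ns)
  if (N - k < 1L) stopf("no residual degrees of freedom")
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1L; df2 <- N - k
  ms_between <- ss_between / df1
  ms_within <- ss_within / df2
  list(ns = ns, means = means, df1 = df1, df2 = df2,
       ms_between = ms_between, ms_within = ms_within)
}

#' One-way ANOVA
#'
#' Standard between/within sums of squares; F with (k-1, N-k) degrees of
#' freedom.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 1 value,
#'   N - k >= 1).
#' @return List: \code{F}, \code{p}, \code{df}, \code{ms_within},
#'   \code{flag} (\code{"F_undefined"} when both between- and
#'   within-group variance are zero).
#' @export
one_way_anova <- function(groups) {
  a <- anova_core(groups)
  if (a$ms_within == 0 && a$ms_between == 0) {
    return(list(F = NA_real_, p = NA_real_, df = c(a$df1, a$df2),
                ms_within = 0, flag = "F_undefined"))
  }
  F <- a$ms_between / a$ms_within
  list(F = F, p = stats::pf(F, a$df1, a$df2, lower.tail = FALSE),
       df = c(a$df1, a$df2), ms_within = a$ms_within, flag = NULL)
}

#' Brown-Forsythe test of variance homogeneity
#'
#' One-way ANOVA on the absolute deviations from each group's median — the
#' median-centred Levene variant, robust to non-normality.
#'
#' @param groups List of numeric vectors, each with n >= 2.
#' @return List: \code{F}, \code{p}, \code{df}.
#' @export
brown_forsythe <- function(groups) {
  if (length(groups) < 2L) stopf("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stopf("each group needs n >= 2")
  dev <- lapply(groups, function(g) abs(g - stats::median(g)))
  res <- one_way_anova(dev)
  # identical spreads give 0/0; deviations carry no evidence against
  # homogeneity, so report F = 0, p = 1
  if (!is.null(res$flag)) return(list(F = 0, p = 1, df = res$df))
  list(F = res$F, p = res$p, df = res$df)
}

#' Holm-Sidak step-down adjustment
#'
#' Raw p-values are sorted ascending; the i-th smallest is adjusted to
#' \code{1 - (1 - p_(i))^(m - i + 1)}, monotonicity is enforced down the
#' sorted list (running maximum), and values are mapped back to input
#' order.
#'
#' @param p Raw p-values in \[0, 1\].
#' @param m Number of comparisons in the family (default
#'   \code{length(p)}).
#' @return Adjusted p-values in input order.
#' @export
holm_sidak <- function(p, m = length(p)) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  if (m < length(p)) stopf("family size m smaller than number of p-values")
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_along(ps) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Dose-versus-control comparisons with Holm-Sidak adjustment
#'
#' The post-ANOVA treatment of the assay dose series: each dose group is
#' compared with the no-protein control by a two-sided pooled-variance t
#' test, with the pooled variance taken as the ANOVA within-group mean
#' square (df = N - k), and the family of raw p-values is Holm-Sidak
#' adjusted with m = number of doses.
#'
#' @param groups Named list of numeric vectors (one per dose group,
#'   including the control).
#' @param control Name of the control group in \code{groups}.
#' @param alpha Family-wise significance level (default 0.05).
#' @return data.frame: group, mean difference from control, t, df, raw and
#'   adjusted p-values, significance flag at \code{alpha}.
#' @export
dunnett_style_vs_control <- function(groups, control, alpha = 0.05) {
  if (!control %in% names(groups)) stopf("control group '%s' missing", control)
  a <- anova_core(groups)
  if (a$ms_within <= 0) stopf("zero within-group variance: t tests undefined")
  doses <- setdiff(names(groups), control)
  nc <- length(groups[[control]])
  mc <- mean(groups[[control]])
  rows <- lapply(doses, function(g) {
    ng <- length(groups[[g]])
    diff <- mean(groups[[g]]) - mc
    se <- sqrt(a$ms_within * (1 / ng + 1 / nc))
    tval <- diff / se
    data.frame(group = g, diff = diff, t = tval, df = a$df2,
               p_raw = 2 * stats::pt(abs(tval), a$df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_sidak(out$p_raw, m = length(doses))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Full statistical treatment of a drift-assay fit
#'
#' Applies the kinetics transforms ([kinetics_transforms()]), checks variance
#' homogeneity ([brown_forsythe()]), runs the one-way ANOVA
#' ([one_way_anova()]) and the Holm-Sidak-adjusted dose-versus-control
#' comparisons ([dunnett_style_vs_control()]) for both normalized
#' nucleation time and normalized calcification rate.
#'
#' @param fit A \code{drift_fit}.
#' @param alpha Family-wise significance level.
#' @return List with one element per metric (\code{nucleation},
#'   \code{rate}), each holding \code{brown_forsythe}, \code{anova} and
#'   \code{comparisons}.
#' @export
dose_response_tests <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "drift_fit"))
  rec <- fit$records
  run_metric <- function(values) {
    keep <- !is.na(values)
    grp <- split(values[keep], rec$dose[keep])
    ctrl <- as.character(rec$dose[rec$role == "control"][1])
    list(brown_forsythe = brown_forsythe(grp[lengths(grp) >= 2]),
         anova = one_way_anova(grp),
         comparisons = dunnett_style_vs_control(grp, control = ctrl,
                                                alpha = alpha))
  }
  tr_nuc <- kinetics_transforms(nucleation = rec$norm_nucleation)$log_nucleation
  tr_rate <- kinetics_transforms(rate = rec$norm_rate)$log_rate
  list(nucleation = run_metric(tr_nuc), rate = run_metric(tr_rate))
}
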