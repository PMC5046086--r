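# Mineral composition from energy dispersive spectroscopy (EDS).

#' Mole percent MgCO3 from elemental atomic fractions
#'
#' Treating carbonate as the only Mg/Ca host phase,
#' \code{mol\% MgCO3 = Mg / (Mg + Ca) * 100}. The measure is invariant to
#' the overall normalization of the atomic fractions, so vendor-quantified
#' fractions and raw count proxies proportional to them give the same
#' answer.
#'
#' @param mg,ca Mg and Ca atomic fractions (or proportional signals),
#'   vectorized.
#' @return mol\% MgCO3, in \[0, 100\].
#' @export
#' @examples
#' mol_percent_mgco3(0.01, 0.03)  # 25
mol_percent_mgco3 <- function(mg, ca) {
  if (any(!is.finite(mg) | !is.finite(ca) | mg < 0 | ca < 0))
    stopf("Mg and Ca signals must be finite and non-negative")
  if (any(mg + ca <= 0)) stopf("Mg + Ca must be positive")
  mg / (mg + ca) * 100
}

#' Average replicate EDS readings per sample
#'
#' EDS readings are taken at random positions within each sample
#' (conventionally three) and averaged; the per-sample means then feed the
#' group statistics.
#'
#' @param eds data.frame with columns \code{sample_id}, \code{mg},
#'   \code{ca} and optionally \code{dose} (see [read_eds()]).
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{dose} (if present), \code{n_readings}, \code{mol_pct_mgco3}
#'   (mean over readings).
#' @export
triplicate_average <- function(eds) {
  eds <- validate_eds(eds)
  eds$mol_pct <- mol_percent_mgco3(eds$mg, eds$ca)
  grp <- split(eds, eds$sample_id)
  out <- do.call(rbind, lapply(grp, function(g) {
    row <- data.frame(sample_id = g$sample_id[1],
                      n_readings = nrow(g),
                      mol_pct_mgco3 = mean(g$mol_pct),
                      stringsAsFactors = FALSE)
    if ("dose" %in% names(g)) row$dose <- g$dose[1]
    row
  }))
  rownames(out) <- NULL
  out
}

#' Dose-group summary of mineral composition
#'
#' Mean and SEM of per-sample mol\% MgCO3 within each dose group.
#'
#' @param samples Output of [triplicate_average()] (must carry a
#'   \code{dose} column).
#' @return data.frame: dose, n, mean_mol_pct, sem_mol_pct.
#' @export
mgco3_dose_summary <- function(samples) {
  if (!"dose" %in% names(samples)) stopf("samples need a dose column")
  grp <- split(samples, samples$dose)
  out <- do.call(rbind, lapply(grp, function(g) data.frame(
    dose = g$dose[1], n = nrow(g),
    mean_mol_pct = mean(g$mol_pct_mgco3),
    sem_mol_pct = if (nrow(g) < 2L) NA_real_ else
      stats::sd(g$mol_pct_mgco3) / sqrt(nrow(g)),
    stringsAsFactors = FALSE
  )))
  rownames(out) <- NULL
  out
}
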