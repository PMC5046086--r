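#' Reaction-volume arithmetic of the micro-modified calcification assay
#'
#' Each assay well is assembled from three additions: bicarbonate buffer,
#' sample (organic matrix diluted in Tris-buffered saline), and calcium
#' buffer. The small total volume is what allows the assay to run in a
#' 96-well plate instead of the several-millilitre vessels classical pH-drift
#' assays need.
#'
#' @param bicarbonate_ul Volume of bicarbonate buffer added, microlitres.
#' @param sample_ul Volume of diluted sample added, microlitres.
#' @param calcium_ul Volume of calcium buffer added, microlitres.
#' @return Total reaction volume in microlitres (default recipe: 200).
#' @seealso [sample_dilution_factor()], [plate_capacity()]
#' @export
#' @examples
#' assay_reaction_volume()  # 200
assay_reaction_volume <- function(bicarbonate_ul = 90, sample_ul = 20,
                                  calcium_ul = 90) {
  vols <- c(bicarbonate_ul, sample_ul, calcium_ul)
  if (any(!is.finite(vols)) || any(vols < 0))
    stopf("volumes must be finite and non-negative")
  sum(vols)
}

#' In-well dilution factor of the sample
#'
#' Samples are prepared at a concentration above the desired final assay
#' concentration because the other reagents dilute them in the well. The
#' factor is total reaction volume over sample volume; with the default
#' 90 + 20 + 90 ul recipe it is 10, which is why stocks are prepared
#' 10-fold concentrated.
#'
#' @inheritParams assay_reaction_volume
#' @return Dimensionless dilution factor (default recipe: 10).
#' @export
sample_dilution_factor <- function(bicarbonate_ul = 90, sample_ul = 20,
                                   calcium_ul = 90) {
  if (sample_ul <= 0) stopf("sample volume must be positive")
  assay_reaction_volume(bicarbonate_ul, sample_ul, calcium_ul) / sample_ul
}

#' Solute fold-concentration from fractional water absorption
#'
#' When a fraction \code{absorbed} of imbibed water is absorbed across the
#' intestinal epithelium while the absolute amount of a solute stays
#' constant, the solute concentration rises by \code{1 / (1 - absorbed)}.
#' At the 85\% absorption typical of marine teleosts this is a roughly
#' seven-fold concentration of the luminal matrix proteins between
#' ingestion and the completion of water absorption.
#'
#' @param absorbed Fraction of water absorbed, in [0, 1).
#' @return Fold change in solute concentration.
#' @export
#' @examples
#' fold_concentration(0.85)  # ~6.67, i.e. approximately seven-fold
fold_concentration <- function(absorbed = 0.85) {
  if (!is.finite(absorbed) || absorbed < 0 || absorbed >= 1)
    stopf("absorbed fraction must lie in [0, 1)")
  1 / (1 - absorbed)
}

#' Sample capacity of a plate given the pH standard series
#'
#' The pH standard curve (7.6 to 9.0 in 0.2-unit increments, i.e. 8 levels)
#' occupies part of the plate; the remaining wells carry samples and
#' controls. With one well per standard level a 96-well plate leaves 88
#' wells for samples.
#'
#' @param n_wells Total wells on the plate.
#' @param ph_min,ph_max,ph_step pH standard series definition.
#' @param replicates Wells per standard level (1 by default; 3 for a
#'   triplicate standard layout).
#' @return Number of wells available for samples and controls.
#' @export
plate_capacity <- function(n_wells = 96, ph_min = 7.6, ph_max = 9.0,
                           ph_step = 0.2, replicates = 1) {
  levels <- standard_ph_series(ph_min, ph_max, ph_step)
  n_std <- length(levels) * replicates
  if (n_std >= n_wells) stopf("standards occupy the whole plate")
  n_wells - n_std
}

#' The canonical pH standard series
#'
#' @inheritParams plate_capacity
#' @return Numeric vector of standard pH levels (default: 7.6, 7.8, ..., 9.0).
#' @export
standard_ph_series <- function(ph_min = 7.6, ph_max = 9.0, ph_step = 0.2) {
  if (ph_step <= 0 || ph_max < ph_min) stopf("invalid pH series definition")
  # seq() accumulates fp error over increments; round to defeat it
  round(seq(ph_min, ph_max, by = ph_step), 10)
}
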