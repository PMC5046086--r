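# Plate layouts and absorbance time series: the shared data model for the
# drift assay. A "plate dataset" is a list(layout, series) where
#   layout: data.frame(well, role, ph_value, sample_id, dose)
#   series: long data.frame(time_s, well, a594)

PLATE_ROLES <- c("standard", "sample", "control", "blank")

canonical_well <- function(well) {
  w <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", w)
  if (any(!ok)) stopf("malformed well id(s): %s",
                      paste(unique(w[!ok]), collapse = ", "))
  w
}

#' Validate a plate layout
#'
#' A layout assigns each well a role (\code{standard}, \code{sample},
#' \code{control} or \code{blank}), a pH value (standards only), a sample
#' label and a protein dose in ug/ml (samples and controls; controls carry
#' dose 0).
#'
#' @param layout data.frame with columns \code{well}, \code{role},
#'   \code{ph_value}, \code{sample_id}, \code{dose}.
#' @param require_control Require at least one control well (needed before
#'   normalization; turn off for standards-only fragments).
#' @return The layout with canonicalized well ids, invisibly classed
#'   \code{plate_layout}.
#' @export
validate_layout <- function(layout, require_control = TRUE) {
  need <- c("well", "role", "ph_value", "sample_id", "dose")
  miss <- setdiff(need, names(layout))
  if (length(miss)) stopf("layout missing column(s): %s",
                          paste(miss, collapse = ", "))
  layout$well <- canonical_well(layout$well)
  if (anyDuplicated(layout$well))
    stopf("duplicate well id(s) in layout")
  bad_role <- setdiff(unique(layout$role), PLATE_ROLES)
  if (length(bad_role)) stopf("unknown role token(s): %s",
                              paste(bad_role, collapse = ", "))
  std <- layout$role == "standard"
  if (any(std & !is.finite(layout$ph_value)))
    stopf("every standard well needs a ph_value")
  sc <- layout$role %in% c("sample", "control")
  if (any(sc & (!is.finite(layout$dose) | layout$dose < 0)))
    stopf("every sample/control well needs a dose >= 0")
  if (require_control && !any(layout$role == "control"))
    stopf("at least one control well is required for normalization")
  class(layout) <- unique(c("plate_layout", class(layout)))
  invisible(layout)
}

validate_series <- function(series) {
  need <- c("time_s", "well", "a594")
  miss <- setdiff(need, names(series))
  if (length(miss)) stopf("series missing column(s): %s",
                          paste(miss, collapse = ", "))
  series$well <- canonical_well(series$well)
  if (anyDuplicated(series[c("time_s", "well")]))
    stopf("duplicate (time, well) rows in series")
  if (!all(is.finite(series$a594))) stopf("non-finite absorbance values")
  for (w in unique(series$well)) {
    tt <- series$time_s[series$well == w]
    if (is.unsorted(tt, strictly = TRUE))
      stopf("times not strictly increasing in well %s", w)
    if (length(tt) < 2L) stopf("well %s has fewer than 2 time points", w)
  }
  series
}

#' Read a plate dataset (layout + absorbance time series)
#'
#' @param layout_path CSV with columns \code{well}, \code{role},
#'   \code{ph_value}, \code{sample_id}, \code{dose}.
#' @param series_path Long-format CSV with columns \code{time_s},
#'   \code{well}, \code{a594} (one row per reading).
#' @param require_control See [validate_layout()].
#' @return A \code{plate_dataset}: \code{list(layout, series)}. Wells present
#'   in the series but absent from the layout are an error; layout wells with
#'   no readings are allowed but flagged in
#'   \code{attr(, "wells_without_data")}.
#' @export
read_plate <- function(layout_path, series_path, require_control = TRUE) {
  layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
  series <- utils::read.csv(series_path, stringsAsFactors = FALSE)
  plate_dataset(layout, series, require_control = require_control)
}

#' Assemble a plate dataset from in-memory tables
#'
#' @param layout,series See [read_plate()] for the required columns.
#' @param require_control See [validate_layout()].
#' @return A \code{plate_dataset} object.
#' @export
plate_dataset <- function(layout, series, require_control = TRUE) {
  layout <- validate_layout(layout, require_control = require_control)
  series <- validate_series(series)
  orphan <- setdiff(unique(series$well), layout$well)
  if (length(orphan))
    stopf("series contains well(s) absent from layout: %s",
          paste(orphan, collapse = ", "))
  silent <- setdiff(layout$well, unique(series$well))
  ds <- structure(list(layout = as.data.frame(layout),
                       series = as.data.frame(series)),
                  class = "plate_dataset")
  attr(ds, "wells_without_data") <- silent
  ds
}

#' Write a plate dataset to layout/series CSV files
#'
#' Round-trips bit-exactly with [read_plate()].
#'
#' @param dataset A \code{plate_dataset}.
#' @param layout_path,series_path Output CSV paths.
#' @export
write_plate <- function(dataset, layout_path, series_path) {
  stopifnot(inherits(dataset, "plate_dataset"))
  utils::write.csv(dataset$layout, layout_path, row.names = FALSE)
  utils::write.csv(dataset$series, series_path, row.names = FALSE)
  invisible(dataset)
}

#' @export
print.plate_dataset <- function(x, ...) {
  tab <- table(x$layout$role)
  cat("Plate dataset:", nrow(x$layout), "wells (",
      paste(sprintf("%s %s", tab, names(tab)), collapse = ", "), ")\n")
  cat("Readings:", nrow(x$series), "over",
      length(unique(x$series$time_s)), "time points\n")
  silent <- attr(x, "wells_without_data")
  if (length(silent))
    cat("Wells without readings:", paste(silent, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a wide plate-reader export to the long series format
#'
#' Plate readers disagree on wide-format dialects, so the long format
#' (\code{time_s}, \code{well}, \code{a594}) is the package's canonical
#' exchange form; this helper converts the common wide shape (one time
#' column, one column per well).
#'
#' @param wide data.frame whose first column is time in seconds and whose
#'   remaining columns are wells named by plate coordinate.
#' @return Long data.frame(time_s, well, a594).
#' @export
wide_to_long <- function(wide) {
  if (ncol(wide) < 2L) stopf("wide table needs a time column and >= 1 well")
  wells <- canonical_well(names(wide)[-1])
  out <- data.frame(
    time_s = rep(wide[[1]], times = length(wells)),
    well = rep(wells, each = nrow(wide)),
    a594 = unlist(wide[-1], use.names = FALSE)
  )
  out[order(out$well, out$time_s), , drop = FALSE]
}

#' Read a pH-stat titration series
#'
#' @param path CSV with columns \code{time_s} and \code{base_ul} (cumulative
#'   NaOH added; any consistent volume or molar unit works).
#' @return data.frame(time_s, base_ul) validated for strictly increasing
#'   times and non-decreasing cumulative base.
#' @export
read_titration <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_titration(x)
}

validate_titration <- function(x) {
  need <- c("time_s", "base_ul")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("titration missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.unsorted(x$time_s, strictly = TRUE))
    stopf("titration times must be strictly increasing")
  if (any(diff(x$base_ul) < 0))
    stopf("cumulative base must be non-decreasing")
  x
}
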