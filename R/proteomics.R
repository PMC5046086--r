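# Matrix-vs-fluid proteomics: spectral-count percentile ranks, protein
# isoelectric points, and acidic-region scanning.

#' Per-sample percentile ranks of spectral counts
#'
#' Within each sample, proteins are ranked ascending by spectral count
#' (ties get the average rank) and rescaled to a 0--100 percentile:
#' \code{(rank - 1) / (n - 1) * 100} over the union protein list, so the
#' least abundant protein sits at 0 and the most abundant at 100. Proteins
#' with zero counts in a sample are set to percentile 0 and marked not
#' detected.
#'
#' @param table A \code{spc_table} from [spc_table()] or
#'   [read_spectral_counts()].
#' @return Numeric matrix (proteins x samples) of percentiles with a
#'   logical attribute \code{detected} of the same shape and the sample
#'   \code{groups} attached.
#' @export
percentile_ranks <- function(table) {
  stopifnot(inherits(table, "spc_table"))
  counts <- table$counts
  n <- nrow(counts)
  pct <- apply(counts, 2, function(v) {
    if (n == 1L) return(0)
    (rank(v, ties.method = "average") - 1) / (n - 1) * 100
  })
  pct <- matrix(pct, nrow = n, dimnames = dimnames(counts))
  detected <- counts > 0
  pct[!detected] <- 0
  attr(pct, "detected") <- detected
  attr(pct, "groups") <- table$groups
  pct
}

#' Matrix-vs-fluid enrichment summary
#'
#' Per protein: the mean percentile rank and its SEM (sd with the n-1
#' denominator over \code{sqrt(n)}) within each sample group, which groups
#' the protein was detected in, and the rank difference
#' (matrix mean - fluid mean). Records are sorted by decreasing rank
#' difference, so matrix-enriched proteins lead the table.
#'
#' @param ranks Percentile matrix from [percentile_ranks()].
#' @param groups Character vector of group tags per sample column; defaults
#'   to the \code{groups} attribute carried by \code{ranks}.
#' @return data.frame: accession, mean_rank_matrix, sem_rank_matrix,
#'   mean_rank_fluid, sem_rank_fluid, detected_in, rank_difference.
#' @export
enrichment_summary <- function(ranks, groups = attr(ranks, "groups")) {
  if (is.null(groups)) stopf("sample group tags required")
  if (length(groups) != ncol(ranks)) stopf("one group tag per sample required")
  if (!all(c("matrix", "fluid") %in% groups))
    stopf("both 'matrix' and 'fluid' groups must have >= 1 sample")
  detected <- attr(ranks, "detected")
  if (is.null(detected)) detected <- ranks > 0
  sem <- function(v) if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  grp_cols <- function(g) which(groups == g)
  mcol <- grp_cols("matrix"); fcol <- grp_cols("fluid")
  out <- data.frame(
    accession = rownames(ranks),
    mean_rank_matrix = rowMeans(ranks[, mcol, drop = FALSE]),
    sem_rank_matrix = apply(ranks[, mcol, drop = FALSE], 1, sem),
    mean_rank_fluid = rowMeans(ranks[, fcol, drop = FALSE]),
    sem_rank_fluid = apply(ranks[, fcol, drop = FALSE], 1, sem),
    detected_in = apply(detected, 1, function(d) {
      paste(sort(unique(groups[d])), collapse = ",")
    }),
    stringsAsFactors = FALSE
  )
  out$rank_difference <- out$mean_rank_matrix - out$mean_rank_fluid
  out <- out[order(-out$rank_difference), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Side-chain / terminal pKa sets. Negative groups: C-terminus, D, E, C, Y;
# positive: N-terminus, K, R, H. X and other letters carry no charge.
PKA_SETS <- list(
  EMBOSS = c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
             D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
  Lehninger = c(Nterm = 9.69, Cterm = 2.34, K = 10.53, R = 12.48, H = 6.0,
                D = 3.65, E = 4.25, C = 8.18, Y = 10.07),
  IPC_protein = c(Nterm = 9.094, Cterm = 2.869, K = 9.052, R = 11.84,
                  H = 5.637, D = 3.872, E = 4.412, C = 7.555, Y = 10.85)
)

POS_GROUPS <- c("Nterm", "K", "R", "H")
NEG_GROUPS <- c("Cterm", "D", "E", "C", "Y")

ionizable_counts <- function(sequence, include_termini = TRUE) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  cnt <- c(Nterm = as.numeric(include_termini),
           Cterm = as.numeric(include_termini),
           K = sum(chars == "K"), R = sum(chars == "R"),
           H = sum(chars == "H"), D = sum(chars == "D"),
           E = sum(chars == "E"), C = sum(chars == "C"),
           Y = sum(chars == "Y"))
  cnt
}

#' Net charge of a protein at a given pH
#'
#' Henderson--Hasselbalch per ionizable group:
#' \code{Z(pH) = sum_pos n_i / (1 + 10^(pH - pKa_i))
#'             - sum_neg n_j / (1 + 10^(pKa_j - pH))},
#' with the N/C termini included by default. \code{Z} is strictly
#' decreasing in pH, so its root (the pI) is unique.
#'
#' @param sequence Amino-acid string (20 standard letters; X ignored).
#' @param ph Numeric pH value(s).
#' @param pka_set Name of the pKa set (\code{"EMBOSS"} default,
#'   \code{"Lehninger"}, \code{"IPC_protein"}) or a named numeric vector
#'   with entries Nterm, Cterm, K, R, H, D, E, C, Y.
#' @param include_termini Include the terminal amine/carboxyl groups.
#' @return Net charge, vectorized over \code{ph}.
#' @export
protein_charge <- function(sequence, ph, pka_set = "EMBOSS",
                           include_termini = TRUE) {
  pka <- if (is.character(pka_set)) {
    if (!pka_set %in% names(PKA_SETS)) stopf("unknown pKa set '%s'", pka_set)
    PKA_SETS[[pka_set]]
  } else pka_set
  cnt <- ionizable_counts(sequence, include_termini)
  z <- numeric(length(ph))
  for (g in POS_GROUPS)
    if (cnt[g] > 0) z <- z + cnt[g] / (1 + 10^(ph - pka[g]))
  for (g in NEG_GROUPS)
    if (cnt[g] > 0) z <- z - cnt[g] / (1 + 10^(pka[g] - ph))
  z
}

#' Isoelectric point of a protein sequence
#'
#' The pH at which the Henderson--Hasselbalch net charge
#' ([protein_charge()]) is zero, found by bisection on \[0, 14\].
#'
#' @inheritParams protein_charge
#' @param tol Bisection tolerance in pH units (default 0.001).
#' @return The pI in pH units; \code{NA} if the sequence carries no
#'   ionizable group at all (cannot happen for a peptide with termini).
#' @export
compute_pI <- function(sequence, pka_set = "EMBOSS", include_termini = TRUE,
                       tol = 0.001) {
  if (!nzchar(sequence)) stopf("empty sequence")
  cnt <- ionizable_counts(sequence, include_termini)
  if (sum(cnt) == 0) return(NA_real_)
  has_pos <- sum(cnt[POS_GROUPS]) > 0
  has_neg <- sum(cnt[NEG_GROUPS]) > 0
  # all groups of one sign: charge never crosses zero inside (0, 14);
  # the root sits at the bracket edge
  lo <- 0; hi <- 14
  z_lo <- protein_charge(sequence, lo, pka_set, include_termini)
  z_hi <- protein_charge(sequence, hi, pka_set, include_termini)
  if (!has_pos && z_lo <= 0) return(0)
  if (!has_neg && z_hi >= 0) return(14)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(sequence, mid, pka_set, include_termini) > 0)
      lo <- mid
    else
      hi <- mid
  }
  (lo + hi) / 2
}

#' Scan a protein for acidic regions
#'
#' Slides a window of \code{window} residues (step 1) along the sequence
#' and computes each window's pI \emph{excluding} the terminal groups (the
#' segment is internal, so terminal charges do not apply). Maximal runs of
#' windows whose pI falls below \code{pI_threshold} are merged into
#' regions.
#'
#' @inheritParams protein_charge
#' @param window Window length in residues (default 39).
#' @param pI_threshold Window-pI cutoff in pH units (default 4.0).
#' @return data.frame with 1-based inclusive \code{start}, \code{end},
#'   \code{length}, \code{window_pI} (minimum window pI inside the region)
#'   and \code{composition} (fraction of D/E residues in the region). Zero
#'   rows when nothing qualifies.
#' @export
acidic_region_scan <- function(sequence, window = 39, pI_threshold = 4.0,
                               pka_set = "EMBOSS") {
  L <- nchar(sequence)
  if (window > L) stopf("window longer than sequence")
  n_win <- L - window + 1L
  win_pi <- vapply(seq_len(n_win), function(s) {
    seg <- substr(sequence, s, s + window - 1L)
    compute_pI(seg, pka_set = pka_set, include_termini = FALSE)
  }, 0)
  qual <- !is.na(win_pi) & win_pi < pI_threshold
  if (!any(qual)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), window_pI = numeric(0),
                      composition = numeric(0)))
  }
  runs <- rle(qual)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  keep <- which(runs$values)
  out <- do.call(rbind, lapply(keep, function(k) {
    s <- starts[k]; e <- stops[k] + window - 1L
    seg <- substr(sequence, s, e)
    chars <- strsplit(seg, "")[[1]]
    data.frame(start = s, end = e, length = e - s + 1L,
               window_pI = min(win_pi[starts[k]:stops[k]]),
               composition = mean(chars %in% c("D", "E")))
  }))
  rownames(out) <- NULL
  out
}

#' Count acidic proteins
#'
#' Number of proteins with an isoelectric point strictly below the cutoff
#' — the classic summary of a biomineralization matrix, where low-pI
#' proteins are the hallmark constituents.
#'
#' @param x Either a numeric vector of pI values or a character vector of
#'   sequences (pIs computed via [compute_pI()]).
#' @param pI_cutoff Cutoff in pH units (default 5.0; strict \code{<}).
#' @param ... Passed to [compute_pI()] when \code{x} is sequences.
#' @return Integer count.
#' @export
count_acidic_proteins <- function(x, pI_cutoff = 5.0, ...) {
  if (is.character(x)) x <- vapply(x, compute_pI, 0, ...)
  sum(x < pI_cutoff, na.rm = TRUE)
}
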