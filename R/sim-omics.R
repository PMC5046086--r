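# Synthetic spectral-count tables and protein sequences with planted
# ground truth.

#' Simulate a spectral-count table with planted matrix enrichment
#'
#' Per-protein baseline abundances are drawn from a log-normal, counts from
#' a negative binomial around them. A planted subset of proteins has its
#' matrix-group mean multiplied by \code{effect}; of these, the first
#' \code{n_matrix_only} are additionally zeroed in every fluid sample
#' (matrix-only proteins, mirroring proteins embedded in the mineral but
#' undetectable in the fluid).
#'
#' @param n_proteins Number of proteins.
#' @param n_matrix,n_fluid Samples per group (conventionally 3 matrix, 2
#'   fluid).
#' @param n_enriched Number of matrix-enriched proteins.
#' @param effect Fold change of the enriched proteins' matrix mean
#'   (1 = null).
#' @param n_matrix_only How many enriched proteins are absent from fluid
#'   (default: all of them).
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline
#'   abundance.
#' @param size Negative-binomial dispersion parameter.
#' @param seed Optional RNG seed; same seed, same table.
#' @return A \code{spc_table} with \code{attr(, "truth")} listing the
#'   enriched and matrix-only accessions.
#' @export
simulate_counts <- function(n_proteins = 100, n_matrix = 3, n_fluid = 2,
                            n_enriched = 13, effect = 20,
                            n_matrix_only = n_enriched,
                            base_meanlog = 2, base_sdlog = 1,
                            size = 5, seed = NULL) {
  if (n_enriched > n_proteins) stopf("n_enriched exceeds n_proteins")
  if (n_matrix_only > n_enriched) stopf("n_matrix_only exceeds n_enriched")
  if (n_matrix < 1L || n_fluid < 1L) stopf("need >= 1 sample per group")
  if (!is.null(seed)) set.seed(seed)
  acc <- sprintf("P%03d", seq_len(n_proteins))
  mu <- stats::rlnorm(n_proteins, base_meanlog, base_sdlog)
  enriched <- acc[seq_len(n_enriched)]
  matrix_only <- acc[seq_len(n_matrix_only)]
  mu_matrix <- mu
  mu_matrix[seq_len(n_enriched)] <- mu_matrix[seq_len(n_enriched)] * effect
  draw <- function(mu_vec, n_col) {
    matrix(stats::rnbinom(n_proteins * n_col, mu = rep(mu_vec, n_col),
                          size = size),
           nrow = n_proteins)
  }
  counts <- cbind(draw(mu_matrix, n_matrix), draw(mu, n_fluid))
  counts[seq_len(n_matrix_only), n_matrix + seq_len(n_fluid)] <- 0L
  rownames(counts) <- acc
  colnames(counts) <- c(sprintf("matrix_%d", seq_len(n_matrix)),
                        sprintf("fluid_%d", seq_len(n_fluid)))
  tab <- spc_table(counts, c(rep("matrix", n_matrix), rep("fluid", n_fluid)))
  attr(tab, "truth") <- list(enriched = enriched, matrix_only = matrix_only)
  tab
}

#' Simulate protein sequences with planted acidic stretches
#'
#' Uniform background residues with homopolymeric plants. The default
#' background alphabet excludes D and E, so an unplanted sequence carries
#' no acidic region at any threshold below the background pI.
#'
#' @param n Number of sequences.
#' @param length Sequence length (residues).
#' @param planted data.frame with columns \code{seq} (1-based sequence
#'   index), \code{start}, \code{len}, \code{residue} (e.g. "E" or "D").
#'   NULL plants nothing. Overlapping plants within a sequence are an
#'   error.
#' @param alphabet Background residues to draw from.
#' @param seed Optional RNG seed.
#' @return Named character vector of sequences with \code{attr(, "truth")}
#'   holding the plant table.
#' @export
simulate_sequences <- function(n = 10, length = 300, planted = NULL,
                               alphabet = setdiff(AA_STANDARD, c("D", "E")),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, length, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- sprintf("seq_%03d", seq_len(n))
  if (!is.null(planted)) {
    need <- c("seq", "start", "len", "residue")
    miss <- setdiff(need, names(planted))
    if (base::length(miss)) stopf("planted table missing: %s",
                                  paste(miss, collapse = ", "))
    for (i in unique(planted$seq)) {
      p <- planted[planted$seq == i, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      ends <- p$start + p$len - 1L
      if (any(ends > length) || any(p$start < 1L))
        stopf("plant outside sequence bounds")
      if (nrow(p) > 1L && any(p$start[-1] <= ends[-nrow(p)]))
        stopf("overlapping plants in sequence %d", i)
      s <- seqs[[i]]
      for (j in seq_len(nrow(p))) {
        substr(s, p$start[j], ends[j]) <-
          strrep(p$residue[j], p$len[j])
      }
      seqs[[i]] <- s
    }
  }
  attr(seqs, "truth") <- planted
  seqs
}
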