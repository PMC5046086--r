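# Spectral-count tables, protein sequences, EDS quantifications.

#' Construct a spectral-count table
#'
#' Spectral counts (SpC) — the number of peptide-spectrum matches assigned
#' to a protein — are a label-free proxy for relative protein abundance.
#' The table holds one row per protein (accession), one column per sample,
#' with a group tag (\code{matrix} or \code{fluid}) per sample.
#'
#' @param counts Integer matrix (proteins x samples) with rownames =
#'   accessions, colnames = sample labels. Missing entries may be NA; they
#'   are zero-filled.
#' @param groups Character vector, one per sample, each \code{"matrix"} or
#'   \code{"fluid"}.
#' @param grouping Optional named character vector mapping accession ->
#'   group label; accessions sharing a label (transcripts of the same
#'   protein) are merged into one row with counts summed. Default: no
#'   grouping.
#' @return A \code{spc_table}: list(counts, groups).
#' @export
spc_table <- function(counts, groups, grouping = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stopf("empty spectral-count table")
  if (is.null(rownames(counts))) stopf("counts need accession rownames")
  counts[is.na(counts)] <- 0L
  if (any(counts < 0)) stopf("negative spectral counts")
  if (any(counts != round(counts))) stopf("non-integer spectral counts")
  storage.mode(counts) <- "integer"
  if (length(groups) != ncol(counts))
    stopf("need one group tag per sample column")
  bad <- setdiff(unique(groups), c("matrix", "fluid"))
  if (length(bad)) stopf("unknown group tag(s): %s", paste(bad, collapse = ", "))
  if (!is.null(grouping)) {
    key <- rownames(counts)
    hit <- key %in% names(grouping)
    key[hit] <- grouping[key[hit]]
    counts <- rowsum(counts, group = key, reorder = FALSE)
    storage.mode(counts) <- "integer"
  }
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate accessions after grouping")
  structure(list(counts = counts, groups = as.character(groups)),
            class = "spc_table")
}

#' Read a spectral-count table from TSV
#'
#' Expected layout: first column \code{accession}; remaining columns one per
#' sample. Group tags come either from an optional second header line
#' starting with \code{#group} (tab-separated tags aligned with the sample
#' columns) or from the \code{groups} argument.
#'
#' @param path TSV file path.
#' @param groups Character vector of group tags, used when the file has no
#'   \code{#group} line.
#' @param grouping See [spc_table()].
#' @return A \code{spc_table}.
#' @export
read_spectral_counts <- function(path, groups = NULL, grouping = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("empty or header-only spectral-count file")
  tag_line <- grepl("^#group", lines)
  if (any(tag_line)) {
    fields <- strsplit(lines[which(tag_line)[1]], "\t", fixed = TRUE)[[1]]
    groups <- fields[-1]
    lines <- lines[!tag_line]
  }
  if (is.null(groups)) stopf("no group tags: supply `groups` or a #group line")
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[-1])
  rownames(counts) <- tab[[1]]
  spc_table(counts, groups, grouping = grouping)
}

#' Write a spectral-count table to TSV (with a #group tag line)
#'
#' @param x A \code{spc_table}.
#' @param path Output path.
#' @export
write_spectral_counts <- function(x, path) {
  stopifnot(inherits(x, "spc_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("accession", colnames(x$counts)), collapse = "\t"), con)
  writeLines(paste(c("#group", x$groups), collapse = "\t"), con)
  utils::write.table(data.frame(accession = rownames(x$counts), x$counts,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(x)
}

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased; a terminal \code{*} (stop) is stripped; an
#' internal \code{*} is an error. Residues outside the 20 standard letters
#' plus \code{X} are rejected or masked as \code{X} per \code{on_invalid}.
#'
#' @param path FASTA file.
#' @param on_invalid \code{"error"} (default) or \code{"mask"}.
#' @return Named character vector of sequences (names = accessions, first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path, on_invalid = c("error", "mask")) {
  on_invalid <- match.arg(on_invalid)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE)
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], ""))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), "")
  clean_sequences(seqs, on_invalid = on_invalid)
}

clean_sequences <- function(seqs, on_invalid = c("error", "mask")) {
  on_invalid <- match.arg(on_invalid)
  seqs <- toupper(seqs)
  seqs <- sub("\\*$", "", seqs)
  if (any(grepl("*", seqs, fixed = TRUE)))
    stopf("internal stop character '*' in sequence")
  if (any(!nzchar(seqs))) stopf("empty sequence")
  legal <- paste0("[^", paste(c(AA_STANDARD, "X"), collapse = ""), "]")
  bad <- grepl(legal, seqs)
  if (any(bad)) {
    if (on_invalid == "error")
      stopf("illegal residue(s) in sequence(s): %s",
            paste(names(seqs)[bad] %||% which(bad), collapse = ", "))
    seqs <- gsub(legal, "X", seqs)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(seqs)
}

#' Read EDS elemental quantifications
#'
#' @param path CSV with columns \code{sample_id}, \code{dose},
#'   \code{reading}, and one column per element with atomic fractions in
#'   [0, 1] (at least \code{mg} and \code{ca}). \code{dose} may be the
#'   string \code{"in_vivo"} for field-collected material.
#' @return Validated data.frame.
#' @export
read_eds <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_eds(x)
}

validate_eds <- function(x) {
  need <- c("sample_id", "mg", "ca")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("EDS table missing column(s): %s",
                          paste(miss, collapse = ", "))
  el <- setdiff(names(x), c("sample_id", "dose", "reading"))
  for (e in el) {
    v <- x[[e]]
    if (any(!is.finite(v) | v < 0 | v > 1))
      stopf("atomic fractions for '%s' must lie in [0, 1]", e)
  }
  if (any(x$mg + x$ca <= 0))
    stopf("Mg + Ca must be positive for ratio computation")
  x
}
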