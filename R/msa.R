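#' Pairwise sequence identity within an alignment
#'
#' Fraction of alignment columns at which both sequences carry the same
#' non-gap residue. The denominator is the full alignment length, so gap
#' columns count against identity: this is the conservative convention
#' used for redundancy weighting, and it makes the measure symmetric and
#' unambiguous.
#'
#' @param a,b [sequence_record()]s (or residue strings) of equal length.
#' @return Identity in `[0, 1]`.
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  a <- as_sequence_record(a); b <- as_sequence_record(b)
  if (nchar(a$residues) != nchar(b$residues))
    abort_data("length mismatch: %d vs %d residues",
               nchar(a$residues), nchar(b$residues))
  va <- strsplit(toupper(a$residues), "")[[1]]
  vb <- strsplit(toupper(b$residues), "")[[1]]
  mean(va == vb & va != "-")
}

#' Number of effective sequences (alignment depth)
#'
#' The redundancy-corrected depth of a multiple sequence alignment, the
#' key predictor of co-evolution contact prediction quality. Each
#' sequence contributes the inverse of its neighborhood size, where the
#' neighborhood of sequence i is the set of sequences (including i
#' itself) at pairwise identity at or above `identity_threshold`:
#'
#' \deqn{N_{eff} = \sum_i 1 / |\{ j : id(i,j) \ge t \}|}
#'
#' A sequence always counts as its own neighbor (even when gaps push
#' its full-length self-identity below the threshold), so every
#' neighborhood is non-empty and `1 <= Neff <= n_sequences`. Identities are computed exactly for all
#' N^2 pairs; alignments of interest here are desk-scale.
#'
#' @param aln A [sequence_file()] with `is_alignment = TRUE`.
#' @param identity_threshold Neighborhood threshold in `(0, 1]`
#'   (default 0.8, the common choice for co-evolution reweighting).
#' @return Neff, a real in `[1, n_sequences]`.
#' @export
effective_sequences <- function(aln, identity_threshold = 0.8) {
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1L ||
      identity_threshold <= 0 || identity_threshold > 1)
    abort_usage("identity_threshold must lie in (0, 1]")
  m <- aln_matrix(aln)
  n <- nrow(m); L <- ncol(m)
  # identity counts via per-letter indicator cross products: O(26 * N^2)
  counts <- matrix(0, n, n)
  for (ch in setdiff(unique(as.vector(m)), "-")) {
    ind <- (m == ch) * 1
    counts <- counts + tcrossprod(ind)
  }
  identity <- counts / L
  hits <- identity >= identity_threshold - 1e-12
  # a sequence is always its own neighbor, even when gaps push its
  # full-length self-identity below the threshold: this keeps every
  # neighborhood non-empty and 1 <= Neff <= N
  diag(hits) <- TRUE
  sum(1 / rowSums(hits))
}

#' Per-column alignment depth
#'
#' @param aln A [sequence_file()] alignment.
#' @return Integer vector, element k = number of sequences with a
#'   non-gap character in column k.
#' @export
per_column_depth <- function(aln) {
  m <- aln_matrix(aln)
  as.integer(colSums(m != "-"))
}

#' Per-sequence coverage
#'
#' @param aln A [sequence_file()] alignment.
#' @return Real vector in `[0, 1]`, element i = fraction of non-gap
#'   positions in sequence i.
#' @export
per_sequence_coverage <- function(aln) {
  m <- aln_matrix(aln)
  rowSums(m != "-") / ncol(m)
}

#' Trim an alignment by coverage
#'
#' Trims to the well-covered core, e.g. the core region of a protein
#' domain: first sequences with coverage below `min_sequence_coverage`
#' are dropped, then columns whose depth among the remaining sequences
#' falls below `min_column_depth_fraction` are dropped. The first
#' sequence is treated as the query and is never dropped, because
#' downstream contact indices refer to it. Original order is preserved;
#' the operation is idempotent at fixed thresholds.
#'
#' @param aln A [sequence_file()] alignment.
#' @param min_sequence_coverage,min_column_depth_fraction Thresholds in
#'   `[0, 1]`.
#' @return The trimmed alignment.
#' @export
trim_by_coverage <- function(aln, min_sequence_coverage = 0.5,
                             min_column_depth_fraction = 0.5) {
  for (t in c(min_sequence_coverage, min_column_depth_fraction))
    if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1)
      abort_usage("trimming thresholds must lie in [0, 1]")
  m <- aln_matrix(aln)
  cov <- rowSums(m != "-") / ncol(m)
  keep_seq <- cov >= min_sequence_coverage
  keep_seq[1] <- TRUE  # query immune
  if (!any(keep_seq))
    abort_data("sequence-coverage filter (%g) removed every sequence",
               min_sequence_coverage)
  m2 <- m[keep_seq, , drop = FALSE]
  depth_frac <- colSums(m2 != "-") / nrow(m2)
  keep_col <- depth_frac >= min_column_depth_fraction
  if (!any(keep_col))
    abort_data("column-depth filter (%g) removed every column",
               min_column_depth_fraction)
  kept <- aln$sequences[keep_seq]
  trimmed <- lapply(kept, function(s) {
    chars <- strsplit(s$residues, "")[[1]][keep_col]
    sequence_record(s$id, paste(chars, collapse = ""))
  })
  sequence_file(aln$id, trimmed, is_alignment = TRUE)
}

#' Summary statistics of an alignment
#'
#' @param aln A [sequence_file()] alignment.
#' @param identity_threshold Passed to [effective_sequences()].
#' @return A list of class `"alignment_stats"` with elements
#'   `n_sequences`, `length`, `neff`, `identity_threshold`,
#'   `per_column_depth`, `per_sequence_coverage`.
#' @export
alignment_stats <- function(aln, identity_threshold = 0.8) {
  m <- aln_matrix(aln)
  structure(
    list(
      n_sequences = nrow(m),
      length = ncol(m),
      neff = effective_sequences(aln, identity_threshold),
      identity_threshold = identity_threshold,
      per_column_depth = per_column_depth(aln),
      per_sequence_coverage = per_sequence_coverage(aln)
    ),
    class = "alignment_stats"
  )
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf(paste0("<alignment_stats> %d sequence(s) x %d column(s)\n",
                     "  neff (threshold %.2f): %.4f\n",
                     "  mean coverage: %.4f\n"),
              x$n_sequences, x$length, x$identity_threshold, x$neff,
              mean(x$per_sequence_coverage)))
  invisible(x)
}
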