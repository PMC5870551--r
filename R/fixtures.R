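# Deterministic synthetic fixtures. Everything here draws from the
# package's portable generator (portable_rng()), never from R's global
# RNG, so the same spec yields byte-identical fixtures on every
# platform and every test input can be generated at run time instead of
# being shipped.

AA_CODES <- unname(AA_THREE_TO_ONE)

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(1, 0, 0))
  v / n
}

rng_unit_sphere <- function(rng) {
  u <- rng$runif(2)
  z <- 2 * u[1] - 1
  phi <- 2 * pi * u[2]
  r <- sqrt(max(0, 1 - z^2))
  c(r * cos(phi), r * sin(phi), z)
}

#' Generate a synthetic folded chain
#'
#' A self-avoiding 3D walk with fixed step length emulating a C-beta
#' trace: successive sites are `step` Angstrom apart, and a bias toward
#' the origin controls how globular the chain becomes. The pull toward
#' the center engages once the walk leaves a target sphere whose radius
#' grows like `length^(1/3)`, with strength proportional to
#' `compactness`: near 0 the chain stays almost straight (contacts only
#' between near-diagonal pairs at an 8 A cutoff); near 1 it folds into
#' a compact globule rich in long-range contacts. Residue names are drawn
#' uniformly from the 20 standard amino acids, so glycines (represented
#' by C-alpha) occur naturally.
#'
#' @param length Number of residues (>= 2).
#' @param seed Seed for the portable generator.
#' @param step Inter-site distance in Angstrom (default 3.8, the
#'   C-alpha virtual bond length).
#' @param compactness Real in `[0, 1]`: weight of the pull toward the
#'   center relative to chain persistence.
#' @param chain Chain identifier used in the sites and PDB output.
#' @return A list with elements `sites` (a `"residue_sites"` data
#'   frame, residues numbered 1..length) and `sequence` (the matching
#'   gap-free [sequence_record()]).
#' @seealso [write_pdb()], [synth_prediction()]
#' @export
synth_chain <- function(length, seed = 1, step = 3.8, compactness = 0.3,
                        chain = "A") {
  if (!is_count(length, min = 2L)) abort_usage("length must be >= 2")
  if (compactness < 0 || compactness > 1)
    abort_usage("compactness must lie in [0, 1]")
  rng <- portable_rng(seed)
  clash <- 0.9 * step
  # target globule radius: scales like length^(1/3) so the center pull
  # only engages once the walk strays outside a sphere that can hold
  # all residues at roughly step spacing
  r0 <- step * max(1, length)^(1 / 3)
  pos <- matrix(NA_real_, length, 3)
  pos[1, ] <- c(0, 0, 0)
  prev_dir <- rng_unit_sphere(rng)
  for (i in 2:length) {
    placed <- FALSE
    for (try in 1:200) {
      noise <- rng_unit_sphere(rng)
      to_center <- -pos[i - 1, ]
      pull <- compactness * min(1, max(0, sqrt(sum(to_center^2)) / r0 - 1))
      dir <- if (try <= 100)
        unit_vec((1 - pull) * prev_dir + pull * unit_vec(to_center) +
                   0.3 * noise)
      else noise  # stuck in a pocket: try fully random directions
      cand <- pos[i - 1, ] + step * dir
      ok <- TRUE
      if (i > 2) {
        d2 <- rowSums((pos[seq_len(i - 2), , drop = FALSE] -
                         matrix(cand, i - 2, 3, byrow = TRUE))^2)
        ok <- all(d2 >= clash^2)
      }
      if (ok) {
        pos[i, ] <- cand
        prev_dir <- dir
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort_data("self-avoidance failed at residue %d; lower compactness", i)
  }
  res_names <- aa_one_to_three(AA_CODES[rng$rint(length, 20)])
  sites <- data.frame(
    chain = chain, residue_number = seq_len(length),
    residue_name = res_names,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    atom_used = ifelse(res_names == "GLY", "CA", "CB"),
    stringsAsFactors = FALSE
  )
  sites <- structure(sites, class = c("residue_sites", "data.frame"))
  list(
    sites = sites,
    sequence = sequence_record("synthetic_chain",
                               paste(aa_three_to_one(res_names),
                                     collapse = ""))
  )
}

#' Write residue sites as a PDB stream
#'
#' Renders one ATOM record per site (fixed-width PDB 3.3 columns) so
#' synthetic chains can be consumed by [read_structure()] and by any
#' other PDB reader.
#'
#' @param sites A `"residue_sites"` data frame.
#' @param file Output path; `NULL` to only return the lines.
#' @return The PDB lines, invisibly.
#' @export
write_pdb <- function(sites, file = NULL) {
  stopifnot(inherits(sites, "residue_sites"))
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    name <- sprintf(" %-3s", sites$atom_used[i])
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, name, sites$residue_name[i], sites$chain[i],
            sites$residue_number[i],
            sites$x[i], sites$y[i], sites$z[i], 1.0, 0.0)
  }, character(1))
  lines <- c(lines, "TER", "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Generate a synthetic contact prediction of known composition
#'
#' Builds a prediction whose true/false-positive composition is
#' constructed exactly, not sampled: `round(tp_fraction * n_predicted)`
#' pairs are drawn without replacement from the reference map (and get
#' the highest scores, descending from 1.0), the remainder are decoys
#' drawn from non-contact pairs at lower scores. Matched against the
#' reference with all residues resolved, the full selection therefore
#' has precision exactly `tp_fraction` (up to the rounding of the TP
#' count).
#'
#' @param reference A canonical [contact_map()] of true contacts.
#' @param n_predicted Total number of predicted pairs (>= 1).
#' @param tp_fraction Fraction of true pairs in `[0, 1]`.
#' @param seed Seed for the portable generator.
#' @param L Target length; defaults to the reference's length.
#' @param min_separation Both true picks and decoys are restricted to
#'   pairs at this separation or more (default 5, matching the
#'   evaluation filter so the constructed composition survives it).
#' @return A [contact_map()] with `length_hint = L`.
#' @export
synth_prediction <- function(reference, n_predicted, tp_fraction,
                             seed = 1, L = NULL, min_separation = 5L) {
  stopifnot(inherits(reference, "contact_map"))
  if (!is_count(n_predicted, min = 1L)) abort_usage("n_predicted must be >= 1")
  if (tp_fraction < 0 || tp_fraction > 1)
    abort_usage("tp_fraction must lie in [0, 1]")
  L <- map_length(reference, L)
  if (is.null(L)) {
    idx <- c(reference$contacts$res1, reference$contacts$res2)
    if (length(idx) == 0) abort_usage("no L known for the reference map")
    L <- max(idx)
  }
  rng <- portable_rng(seed)
  n_tp <- floor(tp_fraction * n_predicted + 0.5)
  n_fp <- n_predicted - n_tp

  ref <- reference$contacts
  pool_tp <- which((ref$res2 - ref$res1) >= min_separation)
  if (n_tp > length(pool_tp))
    abort_data("requested %d true pairs but the reference holds only %d at separation >= %d",
               n_tp, length(pool_tp), min_separation)

  all_pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  sep_ok <- (all_pairs[, 2] - all_pairs[, 1]) >= min_separation
  keys <- paste(all_pairs[, 1], all_pairs[, 2], sep = "_")
  decoy_idx <- which(sep_ok & !(keys %in% pair_key(ref)))
  if (n_fp > length(decoy_idx))
    abort_data("requested %d decoys but only %d non-contact pairs exist",
               n_fp, length(decoy_idx))

  tp_rows <- if (n_tp > 0) pool_tp[rng$sample(seq_along(pool_tp), n_tp)]
             else integer()
  fp_rows <- if (n_fp > 0) decoy_idx[rng$sample(seq_along(decoy_idx), n_fp)]
             else integer()

  res1 <- c(ref$res1[tp_rows], all_pairs[fp_rows, 1])
  res2 <- c(ref$res2[tp_rows], all_pairs[fp_rows, 2])
  scores <- 1.0 - 0.5 * (seq_len(n_predicted) - 1) / n_predicted
  df <- empty_contacts()
  add <- data.frame(
    res1 = as.integer(res1), res2 = as.integer(res2),
    res1_code = "X", res2_code = "X", chain1 = "", chain2 = "",
    raw_score = scores, scaled_score = NA_real_,
    dist_lower = 0, dist_upper = 8, status = "unknown",
    stringsAsFactors = FALSE
  )
  contact_map(id = "synthetic_prediction",
              contacts = structure(add, class = class(df)),
              length_hint = L)
}

#' Generate a synthetic multiple sequence alignment
#'
#' An ancestor sequence is drawn uniformly from the 20 amino acids;
#' each further sequence mutates every position independently with
#' probability `mutation_rate` (to a uniformly chosen different
#' residue) and gaps it with probability `gap_rate`. The first sequence
#' is the ungapped ancestor, playing the role of the query.
#'
#' @param n Number of sequences (>= 1).
#' @param length Alignment length in columns.
#' @param mutation_rate,gap_rate Per-position probabilities in `[0, 1)`.
#' @param seed Seed for the portable generator.
#' @return A [sequence_file()] with `is_alignment = TRUE`.
#' @export
synth_alignment <- function(n, length, mutation_rate = 0.1,
                            gap_rate = 0.05, seed = 1) {
  if (!is_count(n, min = 1L)) abort_usage("n must be >= 1")
  if (!is_count(length, min = 1L)) abort_usage("length must be >= 1")
  for (r in c(mutation_rate, gap_rate))
    if (r < 0 || r >= 1) abort_usage("rates must lie in [0, 1)")
  rng <- portable_rng(seed)
  ancestor <- AA_CODES[rng$rint(length, 20)]
  seqs <- vector("list", n)
  seqs[[1]] <- sequence_record("seq_1", paste(ancestor, collapse = ""))
  for (i in seq_len(n)[-1]) {
    chars <- ancestor
    for (k in seq_len(length)) {
      if (rng$runif(1) < mutation_rate) {
        alt <- setdiff(AA_CODES, chars[k])
        chars[k] <- alt[rng$rint(1, 19)]
      }
      if (rng$runif(1) < gap_rate) chars[k] <- "-"
    }
    seqs[[i]] <- sequence_record(sprintf("seq_%d", i),
                                 paste(chars, collapse = ""))
  }
  sequence_file("synthetic_alignment", seqs, is_alignment = TRUE)
}
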