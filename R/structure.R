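#' Extract representative residue sites from a PDB structure
#'
#' Produces one representative coordinate per residue for contact
#' extraction, following the CASP convention: the C-beta atom, falling
#' back to C-alpha for glycine or when C-beta is missing. Only the first
#' MODEL of multi-model (e.g. NMR) files is used; alternate locations
#' are resolved deterministically by highest occupancy, ties broken
#' alphabetically by altloc code. PDB ATOM records are parsed with
#' bio3d.
#'
#' @param file Path to a PDB file containing ATOM records.
#' @param chain Chain identifier to extract; `NULL` picks the first
#'   chain present.
#' @return A data frame of class `"residue_sites"` with columns `chain`,
#'   `residue_number` (author numbering), `residue_name` (3-letter),
#'   `x`, `y`, `z` (Angstrom) and `atom_used` (`"CB"` or `"CA"`),
#'   ordered by residue number.
#' @export
read_structure <- function(file, chain = NULL) {
  pdb <- tryCatch(
    bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort_data("PDB parse failure: %s",
                                   conditionMessage(e))
  )
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) abort_data("no ATOM records in '%s'", file)
  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    abort_data("chain '%s' absent; available chains: %s", chain,
               paste(chains, collapse = ", "))
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  atoms <- atoms[atoms$elety %in% c("CA", "CB"), , drop = FALSE]
  if (nrow(atoms) == 0)
    abort_data("no CA/CB atoms on chain '%s'", chain)

  pick_alt <- function(df) {
    # highest occupancy, then alphabetical altloc
    occ <- ifelse(is.na(df$o), 1, df$o)
    alt <- ifelse(is.na(df$alt), "", df$alt)
    df[order(-occ, alt), , drop = FALSE][1, , drop = FALSE]
  }

  resnos <- sort(unique(atoms$resno))
  rows <- lapply(resnos, function(rn) {
    res <- atoms[atoms$resno == rn, , drop = FALSE]
    cb <- res[res$elety == "CB", , drop = FALSE]
    use <- if (nrow(cb) > 0) pick_alt(cb)
           else pick_alt(res[res$elety == "CA", , drop = FALSE])
    data.frame(chain = chain, residue_number = rn,
               residue_name = use$resid,
               x = use$x, y = use$y, z = use$z,
               atom_used = use$elety,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, rows)
  if (any(!is.finite(as.matrix(sites[, c("x", "y", "z")]))))
    abort_data("non-finite coordinates on chain '%s'", chain)
  rownames(sites) <- NULL
  structure(sites, class = c("residue_sites", "data.frame"))
}

#' Map structure author numbering onto sequence positions
#'
#' Finds the constant offset that places the structure's residues onto
#' the target sequence: the window of the target whose residue
#' identities match every site exactly (gaps in the author numbering
#' allowed, for unresolved residues). No alignment is attempted -- an
#' exact window match is required, and its absence is an error asking
#' for a manual offset, because silent realignment hides registration
#' bugs. When several windows match, the left-most is used.
#'
#' @param sites A single-chain [read_structure()] result.
#' @param target_sequence A gap-free [sequence_record()] (1-based
#'   positions).
#' @return A named integer vector mapping author residue numbers to
#'   1-based sequence indices; its values are the resolved-index set for
#'   [match_contacts()].
#' @seealso [apply_site_numbering()]
#' @export
renumber_sites <- function(sites, target_sequence) {
  stopifnot(inherits(sites, "residue_sites"))
  if (length(unique(sites$chain)) > 1)
    abort_usage("renumbering requires single-chain sites")
  seq <- as_sequence_record(target_sequence)
  if (grepl("[-.]", seq$residues))
    abort_usage("target sequence must be gap-free")
  chars <- strsplit(toupper(seq$residues), "")[[1]]
  L <- length(chars)
  authors <- sites$residue_number
  codes <- aa_three_to_one(sites$residue_name)
  offsets <- (1 - min(authors)):(L - max(authors))
  for (off in offsets) {
    pos <- authors + off
    if (all(chars[pos] == codes)) {
      mapping <- as.integer(pos)
      names(mapping) <- as.character(authors)
      return(mapping)
    }
  }
  abort_data("structure residues match no window of the target sequence; supply a manual offset with renumber_contacts()")
}

#' Apply a renumbering to residue sites
#'
#' @param sites A [read_structure()] result.
#' @param mapping Output of [renumber_sites()].
#' @return `sites` with `residue_number` replaced by sequence indices.
#' @export
apply_site_numbering <- function(sites, mapping) {
  stopifnot(inherits(sites, "residue_sites"))
  idx <- mapping[as.character(sites$residue_number)]
  if (anyNA(idx)) abort_data("mapping misses %d site(s)", sum(is.na(idx)))
  sites$residue_number <- as.integer(unname(idx))
  sites
}

#' Extract the contact map of a structure
#'
#' Every residue pair whose representative atoms lie within
#' `distance_cutoff` (inclusive) and at sequence separation of at least
#' `min_separation` becomes a contact with `raw_score = 1` and distance
#' bounds `(0, distance_cutoff)`.
#'
#' @param sites A [read_structure()] result (at least 2 sites).
#' @param distance_cutoff Contact distance in Angstrom (default 8.0,
#'   the CASP C-beta convention).
#' @param min_separation Minimum `|i - j|` (default 1 = all pairs).
#' @return A canonical [contact_map()] indexed by the sites'
#'   `residue_number`.
#' @export
contacts_from_structure <- function(sites, distance_cutoff = 8.0,
                                    min_separation = 1L) {
  stopifnot(inherits(sites, "residue_sites"))
  if (nrow(sites) < 2) abort_usage("need at least 2 residue sites")
  d <- as.matrix(stats::dist(sites[, c("x", "y", "z")]))
  idx <- sites$residue_number
  sep <- abs(outer(idx, idx, "-"))
  hit <- which(upper.tri(d) & d <= distance_cutoff & sep >= min_separation,
               arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(contact_map(id = "structure", length_hint = max(idx)))
  df <- empty_contacts()
  add <- data.frame(
    res1 = as.integer(idx[hit[, 1]]), res2 = as.integer(idx[hit[, 2]]),
    res1_code = aa_three_to_one(sites$residue_name[hit[, 1]]),
    res2_code = aa_three_to_one(sites$residue_name[hit[, 2]]),
    chain1 = sites$chain[hit[, 1]], chain2 = sites$chain[hit[, 2]],
    raw_score = 1.0, scaled_score = NA_real_,
    dist_lower = 0, dist_upper = distance_cutoff,
    status = "unknown", stringsAsFactors = FALSE
  )
  df <- structure(add, class = class(df))
  map <- contact_map(id = "structure", contacts = df,
                     length_hint = max(idx))
  sort_contacts(map, "pair_asc")
}

#' Stepwise precision evaluation of a prediction against a structure
#'
#' Reproduces the standard precision-versus-selection-size curve: the
#' prediction is filtered to separations of at least `min_separation`,
#' sorted by score, and for each factor f the top `floor(f * L)`
#' contacts are matched against the structure's contact map (built with
#' the same separation filter, so the comparison is like-for-like).
#' Residues absent from the structure leave their contacts `unknown`
#' and out of the precision denominator. A factor at which no contact
#' can be classified yields `NA` precision (a gap in the curve), not an
#' error.
#'
#' @param predicted A canonical [contact_map()] in the same numbering
#'   frame as `sites` (see [renumber_sites()]).
#' @param sites A [read_structure()] result.
#' @param L Target sequence length; defaults to the map's length.
#' @param factors Strictly increasing positive multipliers of L.
#' @param min_separation Separation filter applied to both maps
#'   (default 5).
#' @param distance_cutoff Contact definition distance (default 8.0 A).
#' @return A data frame of class `"evaluation_result"`, one row per
#'   factor: `factor`, `n_selected`, `n_tp`, `n_fp`, `n_unknown`,
#'   `precision`.
#' @export
evaluate_prediction <- function(predicted, sites, L = NULL,
                                factors = c(0.5, 1.0, 1.5, 2.0),
                                min_separation = 5L,
                                distance_cutoff = 8.0) {
  stopifnot(inherits(predicted, "contact_map"),
            inherits(sites, "residue_sites"))
  if (length(factors) == 0 || any(factors <= 0) ||
      any(diff(factors) <= 0))
    abort_usage("factors must be strictly increasing positive reals")
  L <- map_length(predicted, L)
  if (is.null(L)) abort_usage("no L known: supply L, a length_hint or a sequence")
  reference <- contacts_from_structure(sites, distance_cutoff,
                                       min_separation)
  resolved <- sites$residue_number
  pred <- sort_contacts(remove_neighbors(predicted, min_separation),
                        "raw_score_desc")
  rows <- lapply(factors, function(f) {
    sel <- select_by_l_factor(pred, f, L)
    matched <- match_contacts(sel, reference, resolved)
    tp <- sum(matched$contacts$status == "true_positive")
    fp <- sum(matched$contacts$status == "false_positive")
    unk <- sum(matched$contacts$status == "unknown")
    data.frame(factor = f, n_selected = length(matched),
               n_tp = tp, n_fp = fp, n_unknown = unk,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("evaluation_result", "data.frame"))
}
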