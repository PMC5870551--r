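#' Create a contact map
#'
#' The middle tier of the contact hierarchy: an ordered collection of
#' contacts belonging to one prediction (or one structure), optionally
#' carrying the target sequence and/or an explicit target length.
#'
#' Contacts are canonicalized on construction. Duplicate residue pairs
#' are resolved by the `on_duplicate` policy; the default keeps the
#' first occurrence (with a warning), which in score-sorted prediction
#' files preserves the highest-ranked record.
#'
#' @param id Text label of the map.
#' @param contacts A contact table, e.g. built by [contact()] and
#'   [add_contact()], or a data frame with the same columns.
#' @param sequence Optional [sequence_record()] of the target (gap-free).
#' @param length_hint Optional integer target length L (residues), used
#'   by [select_by_l_factor()] when no sequence is attached.
#' @param on_duplicate Policy for duplicated pairs: `"keep_first"`
#'   (default), `"replace"` (last wins) or `"error"`.
#' @return An object of class `"contact_map"`.
#' @examples
#' m <- contact_map("toy", rbind(contact(1, 5, 0.9), contact(2, 8, 0.4)))
#' length(m)
#' @export
contact_map <- function(id = "", contacts = empty_contacts(),
                        sequence = NULL, length_hint = NULL,
                        on_duplicate = c("keep_first", "replace", "error")) {
  on_duplicate <- match.arg(on_duplicate)
  validate_contacts(contacts)
  contacts <- canonicalize(contacts)
  contacts <- resolve_duplicates(contacts, on_duplicate)
  map <- structure(
    list(id = as.character(id), contacts = contacts,
         sequence = NULL, length_hint = NULL),
    class = "contact_map"
  )
  if (!is.null(length_hint)) {
    if (!is_count(length_hint, min = 1L))
      abort_usage("length_hint must be a positive integer")
    map$length_hint <- as.integer(length_hint)
  }
  if (!is.null(sequence)) map <- assign_sequence(map, sequence)
  map
}

resolve_duplicates <- function(df, policy) {
  key <- pair_key(df)
  if (!anyDuplicated(key)) return(df)
  first_dup <- key[which(duplicated(key))[1]]
  if (policy == "error")
    abort_data("duplicate contact pair (%s)", gsub("_", ", ", first_dup))
  if (policy == "keep_first") {
    warning(sprintf("duplicate contact pair(s) (e.g. %s): keeping first occurrence",
                    gsub("_", ", ", first_dup)), call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  } else {
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' @export
length.contact_map <- function(x) nrow(x$contacts)

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> id='%s', %d contact(s)%s%s\n",
              x$id, length(x),
              if (!is.null(x$sequence))
                sprintf(", sequence '%s'", x$sequence$id) else "",
              if (!is.null(x$length_hint))
                sprintf(", L=%d", x$length_hint) else ""))
  if (length(x) > 0) print(utils::head(x$contacts, 10))
  invisible(x)
}

#' @export
as.data.frame.contact_map <- function(x, ...) {
  df <- x$contacts
  class(df) <- "data.frame"
  df
}

map_length <- function(map, L = NULL) {
  if (!is.null(L)) return(as.integer(L))
  if (!is.null(map$length_hint)) return(map$length_hint)
  if (!is.null(map$sequence)) return(ungapped_length(map$sequence))
  NULL
}

#' Add a contact to a map
#'
#' @param map A [contact_map()].
#' @param x A [contact()] record (canonicalized on insertion).
#' @param on_duplicate What to do when the canonical pair already
#'   exists: keep the existing record, replace it, or raise an error.
#' @return The updated map; insertion order is preserved.
#' @export
add_contact <- function(map, x,
                        on_duplicate = c("keep_first", "replace", "error")) {
  on_duplicate <- match.arg(on_duplicate)
  stopifnot(inherits(map, "contact_map"))
  validate_contacts(x)
  x <- canonicalize(x)
  key <- pair_key(map$contacts)
  new_key <- pair_key(x)
  hit <- match(new_key, key)
  if (is.na(hit)) {
    map$contacts <- rbind(map$contacts, x)
    rownames(map$contacts) <- NULL
  } else if (on_duplicate == "error") {
    abort_data("duplicate contact pair (%d, %d)", x$res1, x$res2)
  } else if (on_duplicate == "replace") {
    map$contacts[hit, ] <- x
  } # keep_first: no-op
  check_indices_against_sequence(map)
  map
}

#' Sort the contacts of a map
#'
#' `raw_score_desc` (the default) sorts by descending raw score,
#' breaking ties by ascending `(res1, res2)` so the ordering is
#' deterministic across platforms. `pair_asc` sorts by residue pair.
#'
#' @param map A [contact_map()].
#' @param key Sorting key.
#' @return The map with contacts reordered.
#' @export
sort_contacts <- function(map, key = c("raw_score_desc", "pair_asc")) {
  key <- match.arg(key)
  df <- map$contacts
  ord <- switch(key,
    raw_score_desc = order(-df$raw_score, df$res1, df$res2),
    pair_asc = order(df$res1, df$res2)
  )
  map$contacts <- df[ord, , drop = FALSE]
  rownames(map$contacts) <- NULL
  map
}

#' Select the n top-scoring contacts
#'
#' Contacts are taken in [sort_contacts()] order (descending raw score,
#' deterministic tie-break). `n` larger than the map simply returns the
#' whole map.
#'
#' @param map A [contact_map()].
#' @param n Number of contacts to keep (`n >= 0`).
#' @return A map holding the selection.
#' @export
top_n <- function(map, n) {
  if (!is_count(n)) abort_usage("n must be a non-negative integer")
  map <- sort_contacts(map, "raw_score_desc")
  map$contacts <- utils::head(map$contacts, n)
  rownames(map$contacts) <- NULL
  map
}

#' Select the top floor(factor * L) contacts
#'
#' Contact predictions are conventionally evaluated on their top
#' `f * L` scored pairs, with L the target sequence length and the
#' product rounded down to the nearest whole number of contacts.
#'
#' @param map A [contact_map()].
#' @param factor Positive multiplier of L (e.g. 0.5, 1, 2).
#' @param L Target length; defaults to the map's `length_hint`, then to
#'   the ungapped length of its sequence. An error if none is known.
#' @return `top_n(map, floor(factor * L))`.
#' @export
select_by_l_factor <- function(map, factor, L = NULL) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    abort_usage("factor must be a positive real")
  L <- map_length(map, L)
  if (is.null(L))
    abort_usage("no L known: supply L, a length_hint or a sequence")
  if (L < 1) abort_usage("L must be >= 1")
  # The 1e-9 guard absorbs binary representation error in factor * L
  # (e.g. 0.7 * 10 = 6.999...) without changing the floor of any
  # genuinely fractional product.
  top_n(map, floor(factor * L + 1e-9))
}

#' Drop short-range contacts
#'
#' Retains contacts whose sequence separation `res2 - res1` is at least
#' `min_separation`; the usual pre-filter before precision evaluation
#' (trivially-near-diagonal pairs carry no information). Order is
#' preserved.
#'
#' @param map A [contact_map()].
#' @param min_separation Minimum separation in residues (default 5, the
#'   common evaluation convention; "long-range" is conventionally >= 23).
#' @return The filtered map.
#' @export
remove_neighbors <- function(map, min_separation = 5L) {
  if (!is_count(min_separation, min = 1L))
    abort_usage("min_separation must be a positive integer")
  keep <- (map$contacts$res2 - map$contacts$res1) >= min_separation
  map$contacts <- map$contacts[keep, , drop = FALSE]
  rownames(map$contacts) <- NULL
  map
}

#' Min-max rescale raw scores into [0, 1]
#'
#' Writes `scaled_score = (raw - min) / (max - min)` for every contact,
#' leaving `raw_score` untouched, so that predictions from methods with
#' different native scales become comparable. When all raw scores are
#' equal the map carries no discriminative information and every
#' `scaled_score` is set to 0 (with a warning).
#'
#' @param map A non-empty [contact_map()].
#' @return The map with `scaled_score` filled in.
#' @export
rescale_scores <- function(map) {
  if (length(map) == 0) abort_usage("cannot rescale an empty map")
  raw <- map$contacts$raw_score
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warning("all raw scores identical; scaled_score set to 0", call. = FALSE)
    map$contacts$scaled_score <- 0
  } else {
    map$contacts$scaled_score <- (raw - rng[1]) / (rng[2] - rng[1])
  }
  map
}

#' Classify predicted contacts against a reference map
#'
#' Compares a predicted map with the contacts extracted from a protein
#' structure (or any reference map) and sets each predicted contact's
#' status: `true_positive` if the pair exists in the reference,
#' `false_positive` if both residues are resolved in the structure but
#' the pair is absent, and `unknown` if either residue is not resolved
#' (an unresolved residue is unevaluable, not wrong). Both maps must
#' already be in the same residue numbering frame; no re-alignment is
#' attempted (see [renumber_contacts()] for a fixed-offset shift).
#'
#' @param predicted,reference Canonical [contact_map()]s in one
#'   numbering frame.
#' @param resolved Integer vector of residue indices resolved in the
#'   reference structure; defaults to every index occurring in
#'   `reference`.
#' @return `predicted` with statuses set; `reference` is not modified.
#' @seealso [precision()]
#' @export
match_contacts <- function(predicted, reference,
                           resolved = unique(c(reference$contacts$res1,
                                               reference$contacts$res2))) {
  stopifnot(inherits(predicted, "contact_map"),
            inherits(reference, "contact_map"))
  ref_key <- pair_key(reference$contacts)
  df <- predicted$contacts
  in_ref <- pair_key(df) %in% ref_key
  both_resolved <- df$res1 %in% resolved & df$res2 %in% resolved
  df$status <- ifelse(in_ref, "true_positive",
                      ifelse(both_resolved, "false_positive", "unknown"))
  predicted$contacts <- df
  predicted
}

#' Precision of a matched contact map
#'
#' `TP / (TP + FP)` over the contacts classified by [match_contacts()].
#' Contacts with `unknown` status (unresolved residues) are excluded
#' from both numerator and denominator.
#'
#' @param matched A map whose statuses have been set by
#'   [match_contacts()].
#' @return Precision in `[0, 1]`.
#' @export
precision <- function(matched) {
  stopifnot(inherits(matched, "contact_map"))
  tp <- sum(matched$contacts$status == "true_positive")
  fp <- sum(matched$contacts$status == "false_positive")
  if (tp + fp == 0)
    abort_data("no classified contacts: nothing to evaluate (all unknown or empty)")
  tp / (tp + fp)
}

#' Count long-range predicted contacts satisfied in a model
#'
#' How many predicted pairs at or above a sequence separation also occur
#' in the contact map of a (structural) model; a simple score for
#' ranking ab initio models by long-range contact fulfilment.
#'
#' @param model_map Contacts extracted from the model.
#' @param predicted Predicted contact map.
#' @param min_separation Minimum `res2 - res1` to count as long-range
#'   (default 23, the conventional long-range boundary).
#' @return Integer count.
#' @export
satisfied_long_range_count <- function(model_map, predicted,
                                       min_separation = 23L) {
  stopifnot(inherits(model_map, "contact_map"),
            inherits(predicted, "contact_map"))
  df <- predicted$contacts
  lr <- (df$res2 - df$res1) >= min_separation
  sum(pair_key(df[lr, , drop = FALSE]) %in% pair_key(model_map$contacts))
}

#' Attach a target sequence to a contact map
#'
#' @param map A [contact_map()].
#' @param seq A gap-free [sequence_record()].
#' @param validate If `TRUE` (default), every contact index must fall
#'   within the sequence and every non-`"X"` residue code must agree
#'   with the sequence at that position; violations are errors naming
#'   the offending position.
#' @return The map with the sequence attached.
#' @export
assign_sequence <- function(map, seq, validate = TRUE) {
  stopifnot(inherits(map, "contact_map"))
  seq <- as_sequence_record(seq)
  if (grepl("[-.]", seq$residues))
    abort_usage("sequence assigned to a contact map must be gap-free")
  map$sequence <- seq
  if (validate) {
    check_indices_against_sequence(map)
    check_codes_against_sequence(map)
  }
  map
}

check_indices_against_sequence <- function(map) {
  if (is.null(map$sequence)) return(invisible(map))
  L <- ungapped_length(map$sequence)
  idx <- c(map$contacts$res1, map$contacts$res2)
  if (length(idx) && max(idx) > L)
    abort_data("contact index %d exceeds sequence length %d", max(idx), L)
  invisible(map)
}

check_codes_against_sequence <- function(map) {
  chars <- strsplit(toupper(map$sequence$residues), "")[[1]]
  df <- map$contacts
  for (side in 1:2) {
    idx <- df[[paste0("res", side)]]
    code <- toupper(df[[paste0("res", side, "_code")]])
    bad <- code != "X" & code != chars[idx]
    if (any(bad)) {
      i <- which(bad)[1]
      abort_data("residue code mismatch at position %d: contact says '%s', sequence says '%s'",
                 idx[i], code[i], chars[idx[i]])
    }
  }
  invisible(map)
}

#' Shift the residue numbering of a map by a fixed offset
#'
#' Helper for bringing a prediction and a structure into one numbering
#' frame when they differ by a constant offset.
#'
#' @param map A [contact_map()].
#' @param offset Integer added to every residue index.
#' @return The renumbered map.
#' @export
renumber_contacts <- function(map, offset) {
  if (!is.numeric(offset) || length(offset) != 1L || offset != floor(offset))
    abort_usage("offset must be an integer")
  map$contacts$res1 <- as.integer(map$contacts$res1 + offset)
  map$contacts$res2 <- as.integer(map$contacts$res2 + offset)
  validate_contacts(map$contacts)
  map
}
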