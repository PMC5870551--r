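CONTACT_STATUS <- c("unknown", "true_positive", "false_positive")

CONTACT_COLUMNS <- c("res1", "res2", "res1_code", "res2_code",
                     "chain1", "chain2", "raw_score", "scaled_score",
                     "dist_lower", "dist_upper", "status")

#' Create a residue-residue contact record
#'
#' The bottom tier of the contact hierarchy: one scored residue pair.
#' Positions are 1-based indices into the target sequence. Contacts are
#' stored in canonical form, `res1 < res2`; self-pairs are rejected at
#' construction because they indicate malformed input.
#'
#' @param res1,res2 1-based residue positions (sequence numbering).
#' @param raw_score Prediction score on the method's native scale.
#' @param res1_code,res2_code One-letter amino-acid codes, `"X"` when
#'   unknown.
#' @param chain1,chain2 Single-character chain identifiers, `""` when
#'   not applicable.
#' @param dist_lower,dist_upper Distance bounds in Angstrom defining the
#'   contact (defaults 0 and 8); `dist_lower` must be strictly below
#'   `dist_upper`.
#' @param scaled_score Score rescaled to `[0, 1]`, `NA` until
#'   [rescale_scores()] is applied.
#' @param status Match status, one of `"unknown"`, `"true_positive"`,
#'   `"false_positive"`; set by [match_contacts()], `"unknown"` before.
#' @return A one-row data frame of class `"contact"`.
#' @seealso [canonicalize()], [contact_map()]
#' @examples
#' contact(5, 3, raw_score = 0.7)   # stored as (3, 5)
#' @export
contact <- function(res1, res2, raw_score = 0,
                    res1_code = "X", res2_code = "X",
                    chain1 = "", chain2 = "",
                    dist_lower = 0, dist_upper = 8,
                    scaled_score = NA_real_, status = "unknown") {
  df <- data.frame(
    res1 = as.integer(res1), res2 = as.integer(res2),
    res1_code = as.character(res1_code), res2_code = as.character(res2_code),
    chain1 = as.character(chain1), chain2 = as.character(chain2),
    raw_score = as.numeric(raw_score),
    scaled_score = as.numeric(scaled_score),
    dist_lower = as.numeric(dist_lower), dist_upper = as.numeric(dist_upper),
    status = as.character(status),
    stringsAsFactors = FALSE
  )
  validate_contacts(df)
  canonicalize(structure(df, class = c("contact", "data.frame")))
}

empty_contacts <- function() {
  structure(
    data.frame(
      res1 = integer(), res2 = integer(),
      res1_code = character(), res2_code = character(),
      chain1 = character(), chain2 = character(),
      raw_score = numeric(), scaled_score = numeric(),
      dist_lower = numeric(), dist_upper = numeric(),
      status = character(),
      stringsAsFactors = FALSE
    ),
    class = c("contact", "data.frame")
  )
}

validate_contacts <- function(df) {
  if (!all(CONTACT_COLUMNS %in% names(df)))
    abort_usage("contact table misses columns: %s",
                paste(setdiff(CONTACT_COLUMNS, names(df)), collapse = ", "))
  if (any(df$res1 < 1L) || any(df$res2 < 1L))
    abort_data("residue indices must be >= 1")
  self <- df$res1 == df$res2
  if (any(self))
    abort_data("self-pair contact (%d, %d) is forbidden",
               df$res1[which(self)[1]], df$res2[which(self)[1]])
  if (any(df$dist_lower >= df$dist_upper))
    abort_data("dist_lower must be strictly below dist_upper")
  bad <- !df$status %in% CONTACT_STATUS
  if (any(bad))
    abort_data("unknown contact status '%s'", df$status[which(bad)[1]])
  invisible(df)
}

#' Put contacts into canonical residue order
#'
#' Canonical form has `res1 < res2`. Rows with `res1 > res2` are
#' swapped, residue codes and chain labels swapped along with them;
#' scores and distance bounds are untouched. Idempotent. Self-pairs are
#' an error.
#'
#' @param x A [contact()] record, or the contact table of a
#'   [contact_map()].
#' @return `x` with every row in canonical order.
#' @examples
#' canonicalize(contact(3, 5, 0.7))
#' @export
canonicalize <- function(x) {
  if (inherits(x, "contact_map")) {
    x$contacts <- canonicalize(x$contacts)
    return(x)
  }
  df <- x
  self <- df$res1 == df$res2
  if (any(self))
    abort_data("self-pair contact (%d, %d) cannot be canonicalized",
               df$res1[which(self)[1]], df$res2[which(self)[1]])
  flip <- df$res1 > df$res2
  if (any(flip)) {
    tmp <- df$res1[flip]; df$res1[flip] <- df$res2[flip]; df$res2[flip] <- tmp
    tmp <- df$res1_code[flip]
    df$res1_code[flip] <- df$res2_code[flip]; df$res2_code[flip] <- tmp
    tmp <- df$chain1[flip]
    df$chain1[flip] <- df$chain2[flip]; df$chain2[flip] <- tmp
  }
  df
}

pair_key <- function(df) paste(df$res1, df$res2, sep = "_")
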