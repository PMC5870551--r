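# Format registry. Every dialect registers a reader (character lines ->
# object), a writer (object -> character lines) and a description of
# which fields of the data model it can represent, so that lossy
# conversions can be reported and round-trip tests know what to expect.

.format_registry <- new.env(parent = emptyenv())

register_format <- function(name, kind, reader, writer, representable,
                            description = "") {
  stopifnot(is_string(name), kind %in% c("contact", "sequence"))
  assign(name, list(name = name, kind = kind, reader = reader,
                    writer = writer, representable = representable,
                    description = description),
         envir = .format_registry)
}

get_format <- function(name) {
  if (!is_string(name) || !exists(name, envir = .format_registry))
    abort_usage("unknown format '%s'; registered formats: %s",
                as.character(name)[1],
                paste(sort(ls(.format_registry)), collapse = ", "))
  get(name, envir = .format_registry)
}

#' List all registered file formats
#'
#' @return A data frame with one row per registered dialect: `name`,
#'   `kind` (`"contact"` or `"sequence"`), `lossy_fields` (contact/
#'   sequence fields the dialect cannot carry, comma-separated) and
#'   `description`.
#' @examples
#' table(format_registry()$kind)
#' @export
format_registry <- function() {
  specs <- lapply(sort(ls(.format_registry)), get, envir = .format_registry)
  all_fields <- c("res1_code", "res2_code", "dist_lower", "dist_upper",
                  "raw_score")
  out <- do.call(rbind, lapply(specs, function(s) {
    lossy <- if (s$kind == "contact")
      setdiff(all_fields, s$representable$cols) else character()
    data.frame(name = s$name, kind = s$kind,
               lossy_fields = paste(lossy, collapse = ","),
               description = s$description,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# --- generic whitespace/CSV columnar contact dialects -----------------

# cols: list of c(field, write_default); field NA_character_ means the
# column exists in the dialect but not in the data model (written as its
# default, ignored on read).
col_spec <- function(field, default = "0") {
  list(field = field, default = default)
}

format_token <- function(field, value) {
  switch(field,
    res1 = , res2 = sprintf("%d", as.integer(value)),
    raw_score = sprintf("%.6f", value),
    dist_lower = , dist_upper = formatC(value, format = "g"),
    as.character(value)
  )
}

parse_token <- function(field, token, lineno) {
  if (field %in% c("res1", "res2")) {
    v <- suppressWarnings(as.integer(token))
    if (is.na(v)) abort_data("line %d: expected an integer, got '%s'",
                             lineno, token)
    return(v)
  }
  if (field %in% c("raw_score", "dist_lower", "dist_upper")) {
    if (grepl(",", token, fixed = TRUE))
      abort_data("line %d: comma decimal '%s' not accepted", lineno, token)
    v <- suppressWarnings(as.numeric(token))
    if (is.na(v)) abort_data("line %d: expected a number, got '%s'",
                             lineno, token)
    return(v)
  }
  token
}

columnar_reader <- function(cols, sep_regex = "[[:space:]]+",
                            comment = "#", skip = 0L,
                            drop_line = function(l) FALSE,
                            fixed_score = NULL) {
  force(cols)
  function(lines, ...) {
    fields <- vapply(cols, `[[`, character(1), "field")
    recs <- list()
    seen <- 0L
    for (i in seq_along(lines)) {
      line <- trimws(lines[i])
      if (!nzchar(line)) next
      if (!is.null(comment) && startsWith(line, comment)) next
      if (drop_line(line)) next
      seen <- seen + 1L
      if (seen <= skip) next
      tokens <- strsplit(line, sep_regex)[[1]]
      if (length(tokens) != length(cols))
        abort_data("line %d: expected %d fields, found %d",
                   i, length(cols), length(tokens))
      rec <- list(raw_score = if (is.null(fixed_score)) 0 else fixed_score)
      for (k in seq_along(cols)) {
        f <- fields[k]
        if (!is.na(f)) rec[[f]] <- parse_token(f, tokens[k], i)
      }
      recs[[length(recs) + 1L]] <- rec
    }
    contacts <- contacts_from_records(recs)
    contact_file(id = "", maps = list(
      contact_map(id = "1", contacts = contacts)
    ))
  }
}

contacts_from_records <- function(recs) {
  if (length(recs) == 0) return(empty_contacts())
  df <- empty_contacts()
  take <- function(f, default) {
    vapply(recs, function(r) r[[f]] %||% default,
           if (is.character(default)) character(1) else numeric(1))
  }
  out <- data.frame(
    res1 = as.integer(take("res1", NA_real_)),
    res2 = as.integer(take("res2", NA_real_)),
    res1_code = take("res1_code", "X"),
    res2_code = take("res2_code", "X"),
    chain1 = "", chain2 = "",
    raw_score = take("raw_score", 0),
    scaled_score = NA_real_,
    dist_lower = take("dist_lower", 0),
    dist_upper = take("dist_upper", 8),
    status = "unknown",
    stringsAsFactors = FALSE
  )
  structure(out, class = class(df))
}

columnar_writer <- function(cols, sep = " ", header = NULL,
                            footer = NULL) {
  force(cols)
  function(obj, ...) {
    map <- single_map_for_write(obj)
    df <- map$contacts
    lines <- character()
    if (!is.null(header)) lines <- c(lines, header)
    if (nrow(df) > 0) {
      body <- vapply(seq_len(nrow(df)), function(r) {
        tokens <- vapply(cols, function(cs) {
          if (is.na(cs$field)) cs$default
          else format_token(cs$field, df[[cs$field]][r])
        }, character(1))
        paste(tokens, collapse = sep)
      }, character(1))
      lines <- c(lines, body)
    }
    c(lines, footer)
  }
}

single_map_for_write <- function(obj) {
  if (inherits(obj, "contact_map")) return(obj)
  stopifnot(inherits(obj, "contact_file"))
  if (length(obj$maps) == 0) abort_data("contact file holds no maps")
  if (length(obj$maps) > 1)
    message("format holds a single contact map: writing the first, dropping ",
            length(obj$maps) - 1L, " other(s)")
  obj$maps[[1]]
}
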