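#' Read a contact or sequence file
#'
#' Single entry point to all registered parsers. The resulting object is
#' the fully populated hierarchy: contacts are canonicalized and
#' duplicate pairs resolved (first occurrence kept, with a warning).
#'
#' @param file Path to the input file (or a connection readable by
#'   [readLines()]). Ignored when `text` is given.
#' @param format Registered format name (see [format_registry()]);
#'   when `NULL`, [sniff_format()] is tried and an error is raised if
#'   the format cannot be determined unambiguously.
#' @param text Optional character vector of lines to parse instead of a
#'   file.
#' @param ... Passed to the format's parser (e.g. `strip_inserts = TRUE`
#'   for A3M).
#' @return A [contact_file()] or [sequence_file()] according to the
#'   format's kind.
#' @examples
#' cf <- read_file(text = "1 9 0 8 0.874", format = "psicov")
#' first_map(cf)$contacts
#' @export
read_file <- function(file = NULL, format = NULL, text = NULL, ...) {
  lines <- if (!is.null(text)) as.character(text) else readLines(file)
  if (length(lines) == 0 || !any(nzchar(trimws(lines))))
    abort_data("empty input stream")
  if (is.null(format)) {
    format <- sniff_format(text = lines)
    if (format == "unknown")
      abort_usage("cannot determine the file format; pass `format` explicitly")
  }
  spec <- get_format(format)
  spec$reader(lines, ...)
}

#' Write a contact or sequence file
#'
#' The inverse of [read_file()]: output written by this function parses
#' back with the same format. Scores are rendered with 6 decimal
#' places. Fields the dialect cannot carry are dropped; see
#' [restrict_to_representable()] to preview the loss.
#'
#' @param obj A [contact_file()], [contact_map()] or [sequence_file()].
#' @param file Output path; `NULL` to only return the lines.
#' @param format Registered format name of matching kind.
#' @param ... Passed to the format's writer.
#' @return The output lines, invisibly.
#' @export
write_file <- function(obj, file = NULL, format = NULL, ...) {
  if (is.null(format)) abort_usage("`format` is required for writing")
  spec <- get_format(format)
  kind <- if (inherits(obj, c("contact_file", "contact_map"))) "contact"
          else if (inherits(obj, "sequence_file")) "sequence"
          else abort_usage("cannot write objects of class '%s'", class(obj)[1])
  if (kind != spec$kind)
    abort_usage("format '%s' holds %s data, but a %s object was given",
                format, spec$kind, kind)
  lines <- spec$writer(obj, ...)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Convert between two file formats
#'
#' A thin wrapper around [read_file()] followed by [write_file()]; both
#' formats must be of the same kind (contact or sequence).
#'
#' @param infile,outfile Input and output paths.
#' @param informat,outformat Registered format names.
#' @param ... Passed to the parser.
#' @return The output lines, invisibly.
#' @export
convert_file <- function(infile, informat, outfile, outformat, ...) {
  in_spec <- get_format(informat)
  out_spec <- get_format(outformat)
  if (in_spec$kind != out_spec$kind)
    abort_usage("cannot convert %s format '%s' into %s format '%s'",
                in_spec$kind, informat, out_spec$kind, outformat)
  obj <- read_file(infile, informat, ...)
  write_file(obj, outfile, outformat)
}

#' Guess the format of a file from structural signatures
#'
#' Best-effort detection: `PFRMAT RR` marks CASP RR, `# STOCKHOLM`
#' marks Stockholm, `>` records mark FASTA (A3M when lowercase insert
#' states are present), and a square symmetric numeric matrix marks
#' CCMpred output. When the signature is ambiguous (e.g. the
#' five-column layouts shared by several dialects) the answer is
#' `"unknown"` rather than a guess.
#'
#' @param file Path to the file; ignored when `text` is given.
#' @param text Optional character vector of lines.
#' @return A registered format name, or `"unknown"`.
#' @export
sniff_format <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) as.character(text) else readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return("unknown")
  first <- trimws(lines[1])
  if (grepl("^PFRMAT[[:space:]]+RR", first)) return("casprr")
  if (grepl("^# STOCKHOLM", first)) return("stockholm")
  if (startsWith(first, ">")) {
    body <- lines[!startsWith(lines, ">")]
    if (any(grepl("[a-z]", body))) return("a3m")
    return("fasta")
  }
  # square symmetric numeric matrix -> ccmpred
  if (length(lines) >= 2 && !startsWith(first, "#")) {
    tokens <- strsplit(trimws(lines), "[[:space:]]+")
    n <- length(lines)
    if (all(vapply(tokens, length, integer(1)) == n)) {
      vals <- suppressWarnings(lapply(tokens, as.numeric))
      if (!anyNA(unlist(vals))) {
        m <- do.call(rbind, vals)
        if (max(abs(m - t(m))) <= 1e-6) return("ccmpred")
      }
    }
  }
  "unknown"
}

#' Restrict an object to the fields a dialect can represent
#'
#' Writing to a lossy format drops information; this helper applies the
#' same loss to an in-memory object, producing what a write/read
#' round-trip through `format` would preserve. Useful to preview a
#' conversion and to state round-trip expectations precisely.
#'
#' @param obj A [contact_file()] or [sequence_file()].
#' @param format Registered format name of matching kind.
#' @return The restricted object.
#' @export
restrict_to_representable <- function(obj, format) {
  spec <- get_format(format)
  if (spec$kind == "contact") {
    stopifnot(inherits(obj, "contact_file"))
    rep <- spec$representable
    maps <- if (rep$multimap) obj$maps else obj$maps[1]
    maps <- lapply(seq_along(maps), function(k) {
      m <- maps[[k]]
      df <- m$contacts
      if (!"raw_score" %in% rep$cols) df$raw_score <- 1.0
      if (!"res1_code" %in% rep$cols) { df$res1_code <- "X"; df$res2_code <- "X" }
      if (!"dist_lower" %in% rep$cols) { df$dist_lower <- 0; df$dist_upper <- 8 }
      df$chain1 <- ""; df$chain2 <- ""
      df$scaled_score <- NA_real_
      df$status <- "unknown"
      out <- contact_map(id = as.character(k), contacts = df,
                         length_hint = if (rep$length) map_length(m))
      if (rep$sequence && !is.null(m$sequence)) {
        out <- assign_sequence(out,
          sequence_record(paste0("model_", k), m$sequence$residues))
      }
      out
    })
    contact_file(
      id = if (spec$representable$meta) (obj$target %||% "") else "",
      maps = maps,
      method = if (rep$meta) obj$method,
      target = if (rep$meta) obj$target,
      remarks = if (rep$meta) obj$remarks else character()
    )
  } else {
    stopifnot(inherits(obj, "sequence_file"))
    seqs <- obj$sequences
    if (format == "jones")
      seqs <- lapply(seq_along(seqs), function(i)
        sequence_record(sprintf("seq_%d", i), seqs[[i]]$residues))
    if (format == "stockholm")
      seqs <- lapply(seqs, function(s)
        sequence_record(gsub("[[:space:]]+", "_", s$id), s$residues))
    seqfile_from_records(seqs)
  }
}
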