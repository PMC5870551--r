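#' Create a contact file (top tier of the hierarchy)
#'
#' A contact file holds one or more contact maps (e.g. the MODEL blocks
#' of a CASP RR submission) plus file-level metadata.
#'
#' @param id Text label.
#' @param maps List of [contact_map()] objects; their `id`s must be
#'   unique within the file.
#' @param method,target Optional free-text metadata.
#' @param remarks Character vector of free-text remarks.
#' @return An object of class `"contact_file"`.
#' @export
contact_file <- function(id = "", maps = list(), method = NULL,
                         target = NULL, remarks = character()) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  stopifnot(all(vapply(maps, inherits, logical(1), "contact_map")))
  ids <- vapply(maps, function(m) m$id, character(1))
  if (anyDuplicated(ids))
    abort_data("duplicate contact map id '%s' within file", ids[duplicated(ids)][1])
  structure(
    list(id = as.character(id), maps = maps,
         method = method, target = target,
         remarks = as.character(remarks)),
    class = "contact_file"
  )
}

#' @export
length.contact_file <- function(x) length(x$maps)

#' @export
print.contact_file <- function(x, ...) {
  cat(sprintf("<contact_file> id='%s', %d map(s)\n", x$id, length(x$maps)))
  for (m in x$maps) print(m)
  invisible(x)
}

#' Extract the first (or only) contact map of a file
#'
#' @param x A [contact_file()].
#' @return The first [contact_map()].
#' @export
first_map <- function(x) {
  stopifnot(inherits(x, "contact_file"))
  if (length(x$maps) == 0) abort_data("contact file '%s' holds no maps", x$id)
  x$maps[[1]]
}

#' Create a sequence record
#'
#' A single (possibly aligned) amino-acid sequence. Gap characters `-`
#' and `.` are both accepted and normalized to `-`; lowercase letters
#' are kept verbatim (A3M insert states).
#'
#' @param id Non-empty identifier.
#' @param residues Non-empty residue string over `A-Z`, `a-z`, `-`.
#' @return An object of class `"sequence_record"`.
#' @export
sequence_record <- function(id, residues) {
  if (!is_string(id) || !nzchar(id)) abort_data("sequence id must be non-empty")
  if (!is_string(residues) || !nzchar(residues))
    abort_data("sequence residues must be non-empty")
  residues <- gsub(".", "-", residues, fixed = TRUE)
  if (grepl("[^A-Za-z-]", residues))
    abort_data("sequence '%s' contains characters outside A-Z, a-z, '-'", id)
  structure(list(id = id, residues = residues), class = "sequence_record")
}

as_sequence_record <- function(x) {
  if (inherits(x, "sequence_record")) return(x)
  if (is_string(x)) return(sequence_record("seq", x))
  abort_usage("expected a sequence_record or a residue string")
}

#' @export
print.sequence_record <- function(x, ...) {
  res <- x$residues
  cat(sprintf("<sequence_record> %s (%d chars)\n  %s%s\n", x$id, nchar(res),
              substr(res, 1, 60), if (nchar(res) > 60) "..." else ""))
  invisible(x)
}

#' Number of non-gap residues in a sequence
#'
#' @param seq A [sequence_record()].
#' @return Integer count of non-`-` characters.
#' @export
ungapped_length <- function(seq) {
  seq <- as_sequence_record(seq)
  nchar(gsub("-", "", seq$residues, fixed = TRUE))
}

#' Create a sequence file (single sequences or an alignment)
#'
#' @param id Text label.
#' @param sequences List of [sequence_record()]s.
#' @param is_alignment If `TRUE`, all residue strings must have equal
#'   length (a rectangular multiple sequence alignment).
#' @return An object of class `"sequence_file"`.
#' @export
sequence_file <- function(id = "", sequences = list(), is_alignment = FALSE) {
  if (inherits(sequences, "sequence_record")) sequences <- list(sequences)
  stopifnot(all(vapply(sequences, inherits, logical(1), "sequence_record")))
  if (is_alignment && length(sequences) > 0) {
    lens <- vapply(sequences, function(s) nchar(s$residues), integer(1))
    if (length(unique(lens)) > 1)
      abort_data("ragged alignment: sequence lengths %s",
                 paste(unique(lens), collapse = ", "))
  }
  structure(
    list(id = as.character(id), sequences = sequences,
         is_alignment = isTRUE(is_alignment),
         remarks = character()),
    class = "sequence_file"
  )
}

#' @export
length.sequence_file <- function(x) length(x$sequences)

#' @export
print.sequence_file <- function(x, ...) {
  cat(sprintf("<sequence_file> id='%s', %d sequence(s)%s\n",
              x$id, length(x), if (x$is_alignment) " [alignment]" else ""))
  invisible(x)
}

# Character matrix view of an alignment (rows = sequences, upper case,
# '.' already normalized to '-').
aln_matrix <- function(aln) {
  stopifnot(inherits(aln, "sequence_file"))
  if (!aln$is_alignment)
    abort_usage("an alignment is required (is_alignment = TRUE)")
  if (length(aln) == 0) abort_data("empty alignment")
  lens <- vapply(aln$sequences, function(s) nchar(s$residues), integer(1))
  if (length(unique(lens)) > 1)
    abort_data("ragged alignment: sequence lengths %s",
               paste(unique(lens), collapse = ", "))
  do.call(rbind, lapply(aln$sequences, function(s)
    strsplit(toupper(s$residues), "")[[1]]))
}
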