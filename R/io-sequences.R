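# The four sequence/alignment formats: FASTA, A3M, Stockholm, JONES.
# FASTA and A3M parsing is delegated to Biostrings; Stockholm and JONES
# are simple enough line formats that they are handled directly (only
# sequence lines and the terminator are honored in Stockholm;
# per-column annotations are kept as opaque remarks on read and are not
# regenerated on write).

fasta_records <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  set <- tryCatch(Biostrings::readBStringSet(tf),
                  error = function(e) abort_data("FASTA parse failure: %s",
                                                 conditionMessage(e)))
  if (length(set) == 0) abort_data("no sequence records found")
  lapply(seq_along(set), function(i)
    sequence_record(names(set)[i], as.character(set[[i]])))
}

seqfile_from_records <- function(seqs, id = "") {
  lens <- vapply(seqs, function(s) nchar(s$residues), integer(1))
  sequence_file(id, seqs,
                is_alignment = length(seqs) > 1 && length(unique(lens)) == 1)
}

read_fasta <- function(lines, ...) {
  seqfile_from_records(fasta_records(lines))
}

write_fasta <- function(obj, width = 60L, ...) {
  stopifnot(inherits(obj, "sequence_file"))
  unlist(lapply(obj$sequences, function(s) {
    starts <- seq(1, nchar(s$residues), by = width)
    c(paste0(">", s$id),
      substring(s$residues, starts, pmin(starts + width - 1L,
                                         nchar(s$residues))))
  }))
}

read_a3m <- function(lines, strip_inserts = FALSE, ...) {
  seqs <- fasta_records(lines)
  if (strip_inserts) {
    seqs <- lapply(seqs, function(s)
      sequence_record(s$id, gsub("[a-z]", "", s$residues)))
  }
  seqfile_from_records(seqs)
}

write_a3m <- function(obj, ...) {
  stopifnot(inherits(obj, "sequence_file"))
  unlist(lapply(obj$sequences, function(s) c(paste0(">", s$id), s$residues)))
}

read_stockholm <- function(lines, ...) {
  if (length(lines) == 0 || !grepl("^# STOCKHOLM", lines[1]))
    abort_data("missing '# STOCKHOLM' header")
  bodies <- list()   # name -> concatenated residues (interleaved blocks)
  order <- character()
  remarks <- character()
  for (i in seq_along(lines)[-1]) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "//")) break
    if (startsWith(line, "#")) {
      remarks <- c(remarks, line)
      next
    }
    tokens <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(tokens) != 2L)
      abort_data("line %d: expected 'name sequence', found %d fields",
                 i, length(tokens))
    nm <- tokens[1]
    if (!nm %in% order) order <- c(order, nm)
    bodies[[nm]] <- paste0(bodies[[nm]] %||% "", tokens[2])
  }
  if (length(order) == 0) abort_data("no sequence lines before '//'")
  seqs <- lapply(order, function(nm) sequence_record(nm, bodies[[nm]]))
  lens <- vapply(seqs, function(s) nchar(s$residues), integer(1))
  if (length(unique(lens)) > 1)
    abort_data("ragged alignment: sequence lengths %s",
               paste(unique(lens), collapse = ", "))
  out <- sequence_file("", seqs, is_alignment = TRUE)
  out$remarks <- remarks
  out
}

write_stockholm <- function(obj, ...) {
  stopifnot(inherits(obj, "sequence_file"))
  lens <- vapply(obj$sequences, function(s) nchar(s$residues), integer(1))
  if (length(unique(lens)) > 1)
    abort_data("Stockholm requires an alignment: sequences of unequal length")
  ids <- vapply(obj$sequences, function(s) s$id, character(1))
  ids <- gsub("[[:space:]]+", "_", ids)
  pad <- max(nchar(ids))
  c("# STOCKHOLM 1.0", "",
    vapply(seq_along(obj$sequences), function(i)
      sprintf("%-*s %s", pad, ids[i], obj$sequences[[i]]$residues),
      character(1)),
    "//")
}

read_jones <- function(lines, ...) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_data("no sequence lines found")
  seqs <- lapply(seq_along(lines), function(i) {
    body <- trimws(lines[i])
    if (grepl("[^A-Za-z.-]", body))
      abort_data("line %d: unexpected characters in sequence", i)
    sequence_record(sprintf("seq_%d", i), body)
  })
  lens <- vapply(seqs, function(s) nchar(s$residues), integer(1))
  if (length(unique(lens)) > 1)
    abort_data("ragged alignment: sequence lengths %s",
               paste(unique(lens), collapse = ", "))
  sequence_file("", seqs, is_alignment = TRUE)
}

write_jones <- function(obj, ...) {
  stopifnot(inherits(obj, "sequence_file"))
  vapply(obj$sequences, function(s) s$residues, character(1))
}

register_sequence_formats <- function() {
  register_format("fasta", "sequence", read_fasta, write_fasta,
    representable(cols = character()),
    "FASTA: '>' header plus wrapped residue lines")
  register_format("a3m", "sequence", read_a3m, write_a3m,
    representable(cols = character()),
    "A3M: FASTA-like, lowercase letters are insert states (kept verbatim; strip_inserts = TRUE removes them)")
  register_format("stockholm", "sequence", read_stockholm, write_stockholm,
    representable(cols = character()),
    "Stockholm 1.0: '# STOCKHOLM' header, 'name sequence' lines, '//' terminator")
  register_format("jones", "sequence", read_jones, write_jones,
    representable(cols = character()),
    "JONES: one aligned sequence per line, no headers (ids are synthesized on read)")
}
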