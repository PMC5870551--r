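# The seventeen contact-prediction dialects. Apart from the CASP RR
# exchange format and the CCMpred square-matrix output, all are
# line-per-contact columnar formats distinguished by their column
# layouts and headers; indices are 1-based throughout and decimal
# points are always '.', never ','.

representable <- function(cols = "raw_score", sequence = FALSE,
                          multimap = FALSE, meta = FALSE, length = FALSE) {
  list(cols = cols, sequence = sequence, multimap = multimap,
       meta = meta, length = length)
}

register_columnar <- function(name, cols, sep = " ",
                              sep_regex = "[[:space:]]+",
                              header = NULL, footer = NULL, skip = 0L,
                              comment = "#", drop_line = function(l) FALSE,
                              fixed_score = NULL, rep = representable(),
                              description = "") {
  register_format(
    name, "contact",
    reader = columnar_reader(cols, sep_regex = sep_regex, comment = comment,
                             skip = skip, drop_line = drop_line,
                             fixed_score = fixed_score),
    writer = columnar_writer(cols, sep = sep, header = header,
                             footer = footer),
    representable = rep,
    description = description
  )
}

# --- CASP RR ----------------------------------------------------------

read_casprr <- function(lines, ...) {
  maps <- list()
  cur <- NULL   # list(id, recs, seq)
  meta <- list(method = NULL, target = NULL, remarks = character())
  flush_map <- function() {
    if (is.null(cur)) return()
    m <- contact_map(id = cur$id, contacts = contacts_from_records(cur$recs))
    if (nzchar(cur$seq))
      m <- assign_sequence(m, sequence_record(paste0("model_", cur$id),
                                              cur$seq))
    maps[[length(maps) + 1L]] <<- m
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    kw <- sub("[[:space:]].*$", "", line)
    rest <- trimws(sub("^[^[:space:]]+", "", line))
    if (kw == "PFRMAT") {
      if (!identical(rest, "RR"))
        abort_data("line %d: PFRMAT is '%s', expected 'RR'", i, rest)
    } else if (kw == "TARGET") {
      meta$target <- rest
    } else if (kw == "METHOD") {
      meta$method <- if (is.null(meta$method)) rest
                     else paste(meta$method, rest)
    } else if (kw == "REMARK") {
      meta$remarks <- c(meta$remarks, rest)
    } else if (kw == "AUTHOR") {
      # carried as a remark so it is not lost silently
      meta$remarks <- c(meta$remarks, paste("AUTHOR", rest))
    } else if (kw == "MODEL") {
      flush_map()
      cur <- list(id = if (nzchar(rest)) rest
                       else as.character(length(maps) + 1L),
                  recs = list(), seq = "")
    } else if (kw %in% c("END", "ENDMDL")) {
      flush_map()
    } else if (grepl("^[A-Za-z-]+$", line)) {
      if (is.null(cur)) cur <- list(id = "1", recs = list(), seq = "")
      cur$seq <- paste0(cur$seq, line)
    } else {
      tokens <- strsplit(line, "[[:space:]]+")[[1]]
      if (length(tokens) != 5L)
        abort_data("line %d: expected 'i j d_lower d_upper score', found %d fields",
                   i, length(tokens))
      if (is.null(cur)) cur <- list(id = "1", recs = list(), seq = "")
      cur$recs[[length(cur$recs) + 1L]] <- list(
        res1 = parse_token("res1", tokens[1], i),
        res2 = parse_token("res2", tokens[2], i),
        dist_lower = parse_token("dist_lower", tokens[3], i),
        dist_upper = parse_token("dist_upper", tokens[4], i),
        raw_score = parse_token("raw_score", tokens[5], i)
      )
    }
  }
  flush_map()
  if (length(maps) == 0)
    maps <- list(contact_map(id = "1"))
  contact_file(id = meta$target %||% "", maps = maps,
               method = meta$method, target = meta$target,
               remarks = meta$remarks)
}

write_casprr <- function(obj, ...) {
  if (inherits(obj, "contact_map")) obj <- contact_file(maps = list(obj))
  stopifnot(inherits(obj, "contact_file"))
  lines <- "PFRMAT RR"
  if (!is.null(obj$target)) lines <- c(lines, paste("TARGET", obj$target))
  for (r in obj$remarks) lines <- c(lines, paste("REMARK", r))
  if (!is.null(obj$method)) lines <- c(lines, paste("METHOD", obj$method))
  maps <- obj$maps
  if (length(maps) == 0) maps <- list(contact_map(id = "1"))
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    lines <- c(lines, paste("MODEL", k))
    if (!is.null(m$sequence)) {
      res <- m$sequence$residues
      starts <- seq(1, nchar(res), by = 50)
      lines <- c(lines, substring(res, starts, pmin(starts + 49, nchar(res))))
    }
    df <- m$contacts
    if (nrow(df) > 0) {
      lines <- c(lines, vapply(seq_len(nrow(df)), function(r) {
        paste(df$res1[r], df$res2[r],
              formatC(df$dist_lower[r], format = "g"),
              formatC(df$dist_upper[r], format = "g"),
              sprintf("%.6f", df$raw_score[r]))
      }, character(1)))
    }
  }
  c(lines, "END")
}

# --- CCMpred square matrix --------------------------------------------

read_ccmpred <- function(lines, ...) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_data("empty matrix stream")
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                              "[[:space:]]+")[[1]]))
    if (anyNA(v)) abort_data("line %d: non-numeric matrix entry", i)
    v
  })
  L <- length(rows)
  if (any(vapply(rows, length, integer(1)) != L))
    abort_data("non-square matrix: %d rows but row lengths %s", L,
               paste(unique(vapply(rows, length, integer(1))), collapse = ","))
  m <- do.call(rbind, rows)
  asym <- abs(m - t(m))
  if (max(asym) > 1e-6)
    warning(sprintf("asymmetric matrix (max |m[i,j] - m[j,i]| = %g); upper triangle wins",
                    max(asym)), call. = FALSE)
  ut <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  recs <- lapply(seq_len(nrow(ut)), function(k) {
    list(res1 = ut[k, 1], res2 = ut[k, 2], raw_score = m[ut[k, 1], ut[k, 2]])
  })
  map <- contact_map(id = "1", contacts = contacts_from_records(recs),
                     length_hint = L)
  map <- sort_contacts(map, "pair_asc")
  contact_file(id = "", maps = list(map))
}

write_ccmpred <- function(obj, ...) {
  map <- single_map_for_write(obj)
  L <- map_length(map)
  if (is.null(L))
    abort_data("matrix output needs a known length: attach a sequence or a length_hint")
  df <- map$contacts
  if (nrow(df) > 0 && max(df$res2) > L)
    abort_data("contact index %d exceeds matrix size %d", max(df$res2), L)
  m <- matrix(0, L, L)
  if (nrow(df) > 0) {
    m[cbind(df$res1, df$res2)] <- df$raw_score
    m[cbind(df$res2, df$res1)] <- df$raw_score
  }
  vapply(seq_len(L), function(i)
    paste(sprintf("%.6f", m[i, ]), collapse = " "), character(1))
}

# --- registry population ----------------------------------------------

register_contact_formats <- function() {
  register_format("casprr", "contact", read_casprr, write_casprr,
    representable(cols = c("raw_score", "dist_lower", "dist_upper"),
                  sequence = TRUE, multimap = TRUE, meta = TRUE),
    "CASP RR exchange format (header, sequence, 'i j d_lower d_upper score', END)")

  register_format("ccmpred", "contact", read_ccmpred, write_ccmpred,
    representable(cols = "raw_score", length = TRUE),
    "CCMpred L x L coupling-score matrix")

  psicov_cols <- list(col_spec("res1"), col_spec("res2"),
                      col_spec("dist_lower"), col_spec("dist_upper"),
                      col_spec("raw_score"))
  register_columnar("psicov", psicov_cols,
    rep = representable(c("raw_score", "dist_lower", "dist_upper")),
    description = "PSICOV output: 'i j 0 8 score'")
  register_columnar("metapsicov", psicov_cols,
    header = "# i j dist_lower dist_upper score",
    rep = representable(c("raw_score", "dist_lower", "dist_upper")),
    description = "MetaPSICOV output: comment header then 'i j 0 8 score'")

  csv_cols <- list(col_spec("res1"), col_spec("res1_code"),
                   col_spec("res2"), col_spec("res2_code"),
                   col_spec(NA_character_, "0"), col_spec("raw_score"))
  register_columnar("evfold", csv_cols, sep = ",", sep_regex = ",",
    rep = representable(c("raw_score", "res1_code", "res2_code")),
    description = "EVfold CSV: 'i,aa_i,j,aa_j,f,score'")
  register_columnar("plmdca", csv_cols, sep = ",", sep_regex = ",",
    rep = representable(c("raw_score", "res1_code", "res2_code")),
    description = "plmDCA CSV: 'i,aa_i,j,aa_j,f,score'")

  register_columnar("freecontact",
    list(col_spec("res1"), col_spec("res1_code"),
         col_spec("res2"), col_spec("res2_code"),
         col_spec(NA_character_, "0.000000"), col_spec("raw_score")),
    rep = representable(c("raw_score", "res1_code", "res2_code")),
    description = "FreeContact output: 'i aa_i j aa_j mi_score score'")

  ijs <- list(col_spec("res1"), col_spec("res2"), col_spec("raw_score"))
  register_columnar("gremlin", ijs, header = "i j score", skip = 1L,
    description = "Gremlin output: one header line then 'i j score'")
  for (fam in c("pconsc", "pconsc2", "pconsc3"))
    register_columnar(fam, ijs,
      header = sprintf("# %s contact predictions", fam),
      description = sprintf("%s output: comment header then 'i j score'", fam))

  register_columnar("epcmap", ijs,
    header = c("PFRMAT EPC-MAP", "MODEL 1"), footer = "END",
    drop_line = function(l) grepl("^(PFRMAT|TARGET|AUTHOR|MODEL|END)", l),
    description = "EPC-Map output: PFRMAT-like preamble then 'i j score'")

  register_columnar("bbcontacts",
    list(col_spec(NA_character_, "pred"), col_spec(NA_character_, "0.306"),
         col_spec(NA_character_, "Antiparallel"), col_spec("raw_score"),
         col_spec(NA_character_, "1"), col_spec(NA_character_, "first"),
         col_spec("res2"), col_spec("res1")),
    header = "#identifier diversity direction viterbiscore indexpred state res2 res1",
    description = "bbcontacts output: beta-beta contact records, pair in the trailing columns")

  register_columnar("bclcontact",
    list(col_spec("res1"), col_spec("res1_code"),
         col_spec("res2"), col_spec("res2_code"),
         col_spec(NA_character_, "0.000000"), col_spec(NA_character_, "0.000000"),
         col_spec(NA_character_, "0.000000"), col_spec(NA_character_, "0.000000"),
         col_spec(NA_character_, "0.000000"), col_spec("raw_score")),
    rep = representable(c("raw_score", "res1_code", "res2_code")),
    description = "BCL::Contact output: five per-type scores then the combined score")

  register_columnar("comsat",
    list(col_spec("res1"), col_spec("res1_code"),
         col_spec("res2"), col_spec("res2_code"),
         col_spec(NA_character_, "Hx-Hy")),
    fixed_score = 1.0,
    rep = representable(cols = c("res1_code", "res2_code")),
    description = "COMSAT output: 'i aa_i j aa_j helix_info', no score (read as 1.0)")

  register_columnar("mempack",
    list(col_spec("res1"), col_spec("res2"), col_spec("raw_score"),
         col_spec(NA_character_, "Hx-Hy")),
    description = "MEMPACK output: 'i j score helix_pair'")

  register_columnar("flib",
    list(col_spec("res1"), col_spec("res1_code"),
         col_spec("res2"), col_spec("res2_code"),
         col_spec("raw_score"), col_spec(NA_character_, "flib")),
    rep = representable(c("raw_score", "res1_code", "res2_code")),
    description = "FLIB output: 'i aa_i j aa_j score source'")
}
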