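# Independent brute-force oracles and randomized fixture builders used
# across the suite. The oracles deliberately use naive loops over pairs
# so they share no code path with the implementation they check.

# precision by explicit per-contact classification
brute_precision <- function(pred_pairs, ref_pairs, resolved) {
  key <- function(p) paste(p[, 1], p[, 2])
  rk <- key(ref_pairs)
  tp <- 0L; fp <- 0L
  for (r in seq_len(nrow(pred_pairs))) {
    i <- pred_pairs[r, 1]; j <- pred_pairs[r, 2]
    if (paste(i, j) %in% rk) tp <- tp + 1L
    else if (i %in% resolved && j %in% resolved) fp <- fp + 1L
  }
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp)
}

# Neff by O(N^2 L) pairwise loops
brute_neff <- function(rows, threshold) {
  n <- length(rows)
  L <- length(rows[[1]])
  neff <- 0
  for (i in seq_len(n)) {
    neighbors <- 1L  # self, unconditionally
    for (j in seq_len(n)) {
      if (j == i) next
      same <- 0L
      for (k in seq_len(L)) {
        if (rows[[i]][k] != "-" && rows[[i]][k] == rows[[j]][k])
          same <- same + 1L
      }
      if (same / L >= threshold) neighbors <- neighbors + 1L
    }
    neff <- neff + 1 / neighbors
  }
  neff
}

# all-pairs contact extraction by explicit loops
brute_structure_contacts <- function(sites, cutoff, min_sep) {
  out <- NULL
  n <- nrow(sites)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      d <- sqrt(sum((as.numeric(sites[a, c("x", "y", "z")]) -
                       as.numeric(sites[b, c("x", "y", "z")]))^2))
      i <- sites$residue_number[a]; j <- sites$residue_number[b]
      if (d <= cutoff && abs(j - i) >= min_sep)
        out <- rbind(out, c(min(i, j), max(i, j)))
    }
  }
  out
}

# random canonical contact map with distinct pairs and 6-dp scores
random_map <- function(rng, n, L, codes = FALSE) {
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pick <- rng$sample(seq_len(nrow(pairs)), min(n, nrow(pairs)))
  df <- as.data.frame(contactr::contact(1, 2))[0, ]
  add <- data.frame(
    res1 = as.integer(pairs[pick, 1]), res2 = as.integer(pairs[pick, 2]),
    res1_code = if (codes) LETTERS[rng$rint(length(pick), 20)] else "X",
    res2_code = if (codes) LETTERS[rng$rint(length(pick), 20)] else "X",
    chain1 = "", chain2 = "",
    raw_score = round(0.1 + 0.9 * rng$runif(length(pick)), 6),
    scaled_score = NA_real_, dist_lower = 0, dist_upper = 8,
    status = "unknown", stringsAsFactors = FALSE
  )
  contact_map(id = "1", contacts = structure(add, class = class(contactr:::empty_contacts())),
              length_hint = L)
}

# random contact_file already restricted to what `format` can carry
random_contact_file <- function(rng, format, n = 8, L = 30) {
  map <- random_map(rng, n, L, codes = TRUE)
  cf <- contact_file(id = "", maps = list(map))
  if (format == "casprr") {
    seq <- paste(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")[
      rng$rint(L, 10)], collapse = "")
    cf$maps[[1]] <- assign_sequence(cf$maps[[1]],
                                    sequence_record("model_1", seq),
                                    validate = FALSE)
    cf$target <- "T0999"
    cf$remarks <- "synthetic fixture"
  }
  restrict_to_representable(cf, format)
}

# random sequence_file restricted to `format`
random_sequence_file <- function(rng, format, n = 5, L = 24) {
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  seqs <- lapply(seq_len(n), function(i) {
    chars <- alpha[rng$rint(L, 20)]
    gaps <- rng$runif(L) < 0.1
    gaps[1] <- FALSE  # keep sequences non-empty and headers simple
    chars[gaps] <- "-"
    sequence_record(sprintf("s%d_%d", i, rng$rint(1, 1000)),
                    paste(chars, collapse = ""))
  })
  restrict_to_representable(sequence_file("", seqs, is_alignment = TRUE),
                            format)
}

# contact table sorted by pair, for order-insensitive comparison
map_table <- function(x) {
  df <- as.data.frame(if (inherits(x, "contact_file")) first_map(x) else x)
  df <- df[order(df$res1, df$res2), ]
  rownames(df) <- NULL
  df
}

seq_table <- function(sf) {
  data.frame(
    id = vapply(sf$sequences, function(s) s$id, character(1)),
    residues = vapply(sf$sequences, function(s) s$residues, character(1)),
    stringsAsFactors = FALSE
  )
}

# the worked 4-sequence alignment: sequences 1 and 2 are mutual
# neighbors at identity 0.9, sequences 3 and 4 are isolated, so
# Neff = 1/2 + 1/2 + 1 + 1 = 3
toy_alignment_neff3 <- function() {
  sequence_file("toy", list(
    sequence_record("s1", "AAAAAAAAAA"),
    sequence_record("s2", "AAAAAAAAAT"),
    sequence_record("s3", "CCCCCCCCCC"),
    sequence_record("s4", "GGGGGGGGGG")
  ), is_alignment = TRUE)
}
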