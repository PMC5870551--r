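test_that("pairwise identity uses the full-length denominator", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("AA--", "AAAA"), 0.5)   # gaps never match
  expect_equal(pairwise_identity("A---", "-AAA"), 0.0)
  expect_equal(pairwise_identity("AB-D", "AB-D"), 0.75)  # shared gap column
  expect_error(pairwise_identity("AAA", "AAAA"), "length mismatch")
  # symmetry
  rng <- portable_rng(3)
  for (k in 1:10) {
    a <- paste(c("A", "C", "-")[rng$rint(12, 3)], collapse = "")
    b <- paste(c("A", "C", "-")[rng$rint(12, 3)], collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("effective_sequences handles the limiting cases and the worked example", {
  identical4 <- sequence_file("i", lapply(1:4, function(i)
    sequence_record(paste0("s", i), "MKVLAW")), is_alignment = TRUE)
  expect_equal(effective_sequences(identical4), 1.0)

  diverse <- sequence_file("d", list(
    sequence_record("s1", "AAAAAAAAAA"),
    sequence_record("s2", "CCCCCCCCCC"),
    sequence_record("s3", "GGGGGGGGGG")
  ), is_alignment = TRUE)
  expect_equal(effective_sequences(diverse), 3.0)

  expect_equal(effective_sequences(toy_alignment_neff3(), 0.8), 3.0)

  expect_error(effective_sequences(diverse, 0), "\\(0, 1\\]")
  ragged <- sequence_file("r", list(sequence_record("a", "MK")),
                          is_alignment = TRUE)
  ragged$sequences[[2]] <- sequence_record("b", "MKV")
  expect_error(effective_sequences(ragged), "ragged")
})

test_that("effective_sequences equals the brute-force oracle and is monotone", {
  rng <- portable_rng(17)
  alpha <- c("A", "C", "D", "E", "-")
  for (k in 1:15) {
    n <- 2 + rng$rint(1, 10)
    L <- 5 + rng$rint(1, 20)
    rows <- lapply(seq_len(n), function(i) alpha[rng$rint(L, 5)])
    aln <- sequence_file("r", lapply(seq_len(n), function(i)
      sequence_record(paste0("s", i), paste(rows[[i]], collapse = ""))),
      is_alignment = TRUE)
    expect_equal(effective_sequences(aln, 0.6), brute_neff(rows, 0.6))
    expect_equal(effective_sequences(aln, 0.9), brute_neff(rows, 0.9))
    # higher threshold -> fewer neighbors -> larger or equal Neff
    expect_lte(effective_sequences(aln, 0.6), effective_sequences(aln, 0.9))
    expect_gte(effective_sequences(aln, 0.6), 1)
    expect_lte(effective_sequences(aln, 0.9), n)
  }
})

test_that("per-column depth and per-sequence coverage count non-gaps", {
  aln <- sequence_file("a", list(sequence_record("x", "AB-"),
                                 sequence_record("y", "A-C")),
                       is_alignment = TRUE)
  expect_equal(per_column_depth(aln), c(2L, 1L, 1L))
  expect_equal(per_sequence_coverage(aln), c(2 / 3, 2 / 3))

  gapless <- sequence_file("g", lapply(1:3, function(i)
    sequence_record(paste0("s", i), "MKVLA")), is_alignment = TRUE)
  expect_equal(per_column_depth(gapless), rep(3L, 5))
  expect_equal(per_sequence_coverage(gapless), rep(1.0, 3))

  allgap <- sequence_file("ag", list(sequence_record("x", "A-A"),
                                     sequence_record("y", "A-A")),
                          is_alignment = TRUE)
  expect_equal(per_column_depth(allgap)[2], 0L)
})

test_that("non-gap characters are conserved between the two views", {
  rng <- portable_rng(29)
  for (k in 1:10) {
    aln <- synth_alignment(3 + rng$rint(1, 10), 10 + rng$rint(1, 30),
                           mutation_rate = 0.3, gap_rate = 0.2,
                           seed = rng$rint(1, 10000))
    L <- nchar(aln$sequences[[1]]$residues)
    expect_equal(sum(per_column_depth(aln)),
                 sum(per_sequence_coverage(aln)) * L)
  }
})

test_that("trim_by_coverage drops sequences then columns, keeps the query", {
  aln <- sequence_file("t", list(sequence_record("q", "ABCD"),
                                 sequence_record("h1", "AB--"),
                                 sequence_record("h2", "AB--")),
                       is_alignment = TRUE)
  trimmed <- trim_by_coverage(aln, 0.4, 0.5)
  expect_equal(length(trimmed), 3L)                 # all coverages >= 0.4
  expect_equal(nchar(trimmed$sequences[[1]]$residues), 2L)  # cols 3,4 dropped
  expect_equal(trimmed$sequences[[1]]$residues, "AB")

  # identity at zero thresholds
  un <- trim_by_coverage(aln, 0, 0)
  expect_equal(seq_table(un), seq_table(aln))

  # an all-gap non-query sequence is removed
  aln2 <- sequence_file("t2", list(sequence_record("q", "ABCD"),
                                   sequence_record("junk", "----")),
                        is_alignment = TRUE)
  expect_equal(length(trim_by_coverage(aln2, 0.1, 0)), 1L)

  # the query survives even below the coverage threshold
  aln3 <- sequence_file("t3", list(sequence_record("q", "A---"),
                                   sequence_record("h", "ABCD")),
                        is_alignment = TRUE)
  expect_equal(seq_table(trim_by_coverage(aln3, 0.9, 0))$id, c("q", "h"))

  expect_error(trim_by_coverage(aln2, 0, 1.01), "\\[0, 1\\]")
})

test_that("trim_by_coverage is idempotent at fixed thresholds", {
  rng <- portable_rng(31)
  for (k in 1:5) {
    aln <- synth_alignment(8, 30, mutation_rate = 0.2, gap_rate = 0.3,
                           seed = rng$rint(1, 10000))
    once <- trim_by_coverage(aln, 0.6, 0.5)
    twice <- trim_by_coverage(once, 0.6, 0.5)
    expect_equal(seq_table(twice), seq_table(once))
  }
})

test_that("alignment_stats aggregates the individual statistics", {
  aln <- toy_alignment_neff3()
  st <- alignment_stats(aln, 0.8)
  expect_equal(st$n_sequences, 4L)
  expect_equal(st$length, 10L)
  expect_equal(st$neff, 3.0)
  expect_equal(st$per_column_depth, per_column_depth(aln))
  expect_equal(st$per_sequence_coverage, per_sequence_coverage(aln))
  expect_true(st$neff >= 1 && st$neff <= st$n_sequences)
})
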