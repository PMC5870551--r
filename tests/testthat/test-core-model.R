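test_that("contacts are canonicalized and self-pairs rejected", {
  c1 <- contact(5, 3, raw_score = 0.7, res1_code = "K", res2_code = "M",
                chain1 = "A", chain2 = "B")
  expect_equal(c1$res1, 3L)
  expect_equal(c1$res2, 5L)
  expect_equal(c1$res1_code, "M")  # codes travel with their residue
  expect_equal(c1$res2_code, "K")
  expect_equal(c1$chain1, "B")
  expect_equal(c1$raw_score, 0.7)

  c2 <- contact(3, 5, 0.7)
  expect_identical(canonicalize(c2), c2)

  expect_error(contact(4, 4), "self-pair.*\\(4, 4\\)")
  expect_error(contact(0, 5), "indices")
  expect_error(contact(1, 5, dist_lower = 9, dist_upper = 8), "dist_lower")
})

test_that("canonicalization is idempotent on random pairs", {
  rng <- portable_rng(11)
  for (k in 1:50) {
    i <- rng$rint(1, 100); j <- rng$rint(1, 100)
    if (i == j) next
    c1 <- canonicalize(contact(i, j, rng$runif(1)))
    expect_identical(canonicalize(c1), c1)
    expect_lt(c1$res1, c1$res2)
  }
})

test_that("add_contact applies duplicate policies after canonicalization", {
  m <- add_contact(contact_map("m"), contact(3, 5, 0.7))
  expect_equal(length(m), 1L)

  kept <- add_contact(m, contact(3, 5, 0.9), "keep_first")
  expect_equal(kept$contacts$raw_score, 0.7)

  # the duplicate arrives in swapped order; replacement must still fire
  repl <- add_contact(m, contact(5, 3, 0.9), "replace")
  expect_equal(length(repl), 1L)
  expect_equal(repl$contacts$raw_score, 0.9)
  expect_equal(repl$contacts$res1, 3L)

  expect_error(add_contact(m, contact(5, 3, 0.9), "error"), "duplicate")
})

test_that("sorting is deterministic with documented tie-break", {
  m <- contact_map("m", rbind(contact(7, 9, 0.5), contact(2, 8, 0.5),
                              contact(1, 4, 0.9)))
  s <- sort_contacts(m, "raw_score_desc")
  expect_equal(s$contacts$raw_score, c(0.9, 0.5, 0.5))
  expect_equal(s$contacts$res1[2:3], c(2L, 7L))  # equal scores: pair order

  p <- sort_contacts(m, "pair_asc")
  expect_equal(p$contacts$res1, c(1L, 2L, 7L))

  empty <- sort_contacts(contact_map("e"))
  expect_equal(length(empty), 0L)
})

test_that("top_n clamps, rejects negatives, and nests monotonically", {
  rng <- portable_rng(5)
  m <- random_map(rng, 20, 40)
  expect_equal(length(top_n(m, 0)), 0L)
  expect_equal(length(top_n(m, 99)), 20L)
  expect_error(top_n(m, -1), "non-negative")

  two <- top_n(m, 2)
  expect_equal(two$contacts$raw_score,
               sort(m$contacts$raw_score, decreasing = TRUE)[1:2])
  for (a in c(1, 5, 10)) {
    small <- contactr:::pair_key(top_n(m, a)$contacts)
    big <- contactr:::pair_key(top_n(m, a + 7)$contacts)
    expect_true(all(small %in% big))
  }
})

test_that("select_by_l_factor implements the floor rule", {
  rng <- portable_rng(6)
  m <- random_map(rng, 150, 60)
  expect_equal(length(select_by_l_factor(m, 1.0, L = 100)), 100L)
  expect_equal(length(select_by_l_factor(m, 0.5, L = 57)), 28L)   # floor(28.5)
  expect_equal(length(select_by_l_factor(m, 0.05, L = 10)), 0L)   # floor(0.5)
  # length taken from length_hint when L not given
  expect_equal(length(select_by_l_factor(m, 0.5)), 30L)

  bare <- contact_map("no_length", rbind(contact(1, 5, 1)))
  expect_error(select_by_l_factor(bare, 1.0), "no L known")
})

test_that("remove_neighbors keeps pairs at or above the separation", {
  m <- contact_map("m", rbind(contact(10, 12, 1), contact(10, 20, 1),
                              contact(1, 5, 1), contact(1, 6, 1)))
  out <- remove_neighbors(m, 5)
  # separation of (1,5) is 4, below the inclusive >= 5 boundary
  expect_equal(contactr:::pair_key(out$contacts), c("10_20", "1_5", "1_6")[-2])
  expect_equal(length(remove_neighbors(m, 1)), 4L)  # identity at 1
})

test_that("rescale_scores is min-max, rank preserving, raw untouched", {
  m <- contact_map("m", rbind(contact(1, 5, 2), contact(2, 6, 4),
                              contact(3, 7, 6)))
  r <- rescale_scores(m)
  expect_equal(r$contacts$scaled_score, c(0, 0.5, 1))
  expect_equal(r$contacts$raw_score, c(2, 4, 6))

  shifted <- contact_map("m", rbind(contact(1, 5, -1), contact(2, 6, 0),
                                    contact(3, 7, 1)))
  expect_equal(rescale_scores(shifted)$contacts$scaled_score, c(0, 0.5, 1))

  one <- contact_map("m", rbind(contact(1, 5, 3.7)))
  expect_warning(one <- rescale_scores(one), "identical")
  expect_equal(one$contacts$scaled_score, 0)

  rng <- portable_rng(9)
  big <- rescale_scores(random_map(rng, 30, 50))
  expect_equal(order(big$contacts$raw_score), order(big$contacts$scaled_score))
})

test_that("match_contacts classifies tp/fp/unknown by resolved residues", {
  ref <- contact_map("ref", rbind(contact(1, 9, 1)))
  resolved <- 1:10

  tp <- match_contacts(contact_map("p", rbind(contact(1, 9, 1))), ref, resolved)
  expect_equal(tp$contacts$status, "true_positive")

  fp <- match_contacts(contact_map("p", rbind(contact(2, 8, 1))), ref, resolved)
  expect_equal(fp$contacts$status, "false_positive")

  unk <- match_contacts(contact_map("p", rbind(contact(2, 11, 1))), ref, resolved)
  expect_equal(unk$contacts$status, "unknown")
})

test_that("precision excludes unknowns and rejects empty classifications", {
  ref <- contact_map("ref", rbind(contact(1, 9, 1), contact(2, 9, 1)))
  p <- contact_map("p", rbind(
    contact(1, 9, 1), contact(2, 9, 1),             # TP, TP
    contact(3, 8, 1),                               # FP
    contact(3, 30, 1), contact(4, 31, 1), contact(5, 32, 1),
    contact(6, 33, 1), contact(7, 34, 1), contact(2, 35, 1),
    contact(1, 36, 1)                               # 7 unknown
  ))
  matched <- match_contacts(p, ref, resolved = 1:10)
  expect_equal(sum(matched$contacts$status == "unknown"), 7L)
  expect_equal(precision(matched), 2 / 3)

  all_unknown <- match_contacts(contact_map("p", rbind(contact(20, 30, 1))),
                                ref, resolved = 1:10)
  expect_error(precision(all_unknown), "nothing to evaluate")
})

test_that("self-match precision is 1 and matches the brute-force oracle", {
  rng <- portable_rng(21)
  for (k in 1:20) {
    P <- random_map(rng, 3 + rng$rint(1, 30), 50)
    expect_equal(precision(match_contacts(P, P, resolved = 1:50)), 1.0)

    Q <- random_map(rng, 3 + rng$rint(1, 30), 50)
    resolved <- which(rng$runif(50) < 0.8)
    got <- tryCatch(precision(match_contacts(P, Q, resolved)),
                    error = function(e) NA_real_)
    want <- brute_precision(as.matrix(P$contacts[, c("res1", "res2")]),
                            as.matrix(Q$contacts[, c("res1", "res2")]),
                            resolved)
    expect_identical(got, want)
  }
})

test_that("satisfied_long_range_count filters separation then intersects", {
  model <- contact_map("mod", rbind(contact(1, 30, 1), contact(2, 40, 1)))
  pred <- contact_map("p", rbind(contact(1, 30, 1), contact(1, 3, 1)))
  expect_equal(satisfied_long_range_count(model, pred, 23), 1L)
  expect_equal(satisfied_long_range_count(model, model, 23), 2L)
  disjoint <- contact_map("d", rbind(contact(5, 50, 1)))
  expect_equal(satisfied_long_range_count(model, disjoint, 23), 0L)
})

test_that("assign_sequence validates range and residue codes", {
  m <- contact_map("m", rbind(contact(1, 5, 1)))
  ok <- assign_sequence(m, sequence_record("t", "MKVLA"))
  expect_equal(ok$sequence$id, "t")

  m6 <- contact_map("m", rbind(contact(1, 6, 1)))
  expect_error(assign_sequence(m6, sequence_record("t", "MKVLA")),
               "exceeds sequence length 5")

  mm <- contact_map("m", rbind(contact(1, 5, 1, res1_code = "M")))
  expect_error(assign_sequence(mm, sequence_record("t", "KKVLA")),
               "position 1")
  expect_error(assign_sequence(m, sequence_record("t", "MK-LA")),
               "gap-free")
})

test_that("renumber_contacts shifts both indices", {
  m <- contact_map("m", rbind(contact(3, 9, 1)))
  shifted <- renumber_contacts(m, -2)
  expect_equal(shifted$contacts$res1, 1L)
  expect_equal(shifted$contacts$res2, 7L)
  expect_error(renumber_contacts(m, -5), "indices")
})
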