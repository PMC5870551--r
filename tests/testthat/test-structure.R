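# Handwritten PDB fragments exercising the extraction policies.
pdb_fixture <- function(lines, file = withr::local_tempfile(fileext = ".pdb",
                                                            .local_envir = parent.frame())) {
  writeLines(lines, file)
  file
}

atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                      occ = 1.0, alt = " ") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0.0)
}

test_that("C-beta is preferred with C-alpha fallback for glycine", {
  f <- pdb_fixture(c(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "CB", "ALA", "A", 1, 1, 0, 0),
    atom_line(3, "CA", "GLY", "A", 2, 5, 0, 0),
    "TER", "END"
  ))
  sites <- read_structure(f, "A")
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$atom_used, c("CB", "CA"))
  expect_equal(sites$x, c(1, 5))
  expect_equal(sites$residue_name, c("ALA", "GLY"))
})

test_that("altloc is resolved by occupancy then alphabetically", {
  f <- pdb_fixture(c(
    atom_line(1, "CB", "ALA", "A", 1, 1, 0, 0, occ = 0.4, alt = "A"),
    atom_line(2, "CB", "ALA", "A", 1, 2, 0, 0, occ = 0.6, alt = "B"),
    atom_line(3, "CB", "VAL", "A", 2, 5, 0, 0, occ = 0.5, alt = "B"),
    atom_line(4, "CB", "VAL", "A", 2, 6, 0, 0, occ = 0.5, alt = "A"),
    "END"
  ))
  sites <- read_structure(f, "A")
  expect_equal(sites$x, c(2, 6))  # occupancy winner, then altloc 'A' on tie
})

test_that("only the first MODEL of an ensemble is read", {
  f <- pdb_fixture(c(
    "MODEL        1",
    atom_line(1, "CB", "ALA", "A", 1, 1, 0, 0),
    atom_line(2, "CB", "VAL", "A", 2, 5, 0, 0),
    "ENDMDL",
    "MODEL        2",
    atom_line(1, "CB", "ALA", "A", 1, 99, 0, 0),
    atom_line(2, "CB", "VAL", "A", 2, 99, 9, 0),
    "ENDMDL", "END"
  ))
  sites <- read_structure(f)
  expect_equal(sites$x, c(1, 5))
})

test_that("missing chains and structures without atoms are rejected", {
  f <- pdb_fixture(c(atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0), "END"))
  expect_error(read_structure(f, "B"), "chain 'B' absent")
})

test_that("renumber_sites finds the exact sequence window", {
  f <- pdb_fixture(c(
    atom_line(1, "CB", "MET", "A", 12, 0, 0, 0),
    atom_line(2, "CB", "LYS", "A", 13, 4, 0, 0),
    atom_line(3, "CB", "VAL", "A", 14, 8, 0, 0),
    atom_line(4, "CB", "LEU", "A", 15, 12, 0, 0),
    atom_line(5, "CB", "ALA", "A", 16, 16, 0, 0),
    "END"
  ))
  sites <- read_structure(f, "A")
  mapping <- renumber_sites(sites, sequence_record("t", "GGMKVLAGG"))
  expect_equal(unname(mapping), 3:7)
  expect_equal(names(mapping), as.character(12:16))

  # author numbering already 1..L with the identical sequence
  f2 <- pdb_fixture(c(
    atom_line(1, "CB", "MET", "A", 1, 0, 0, 0),
    atom_line(2, "CB", "LYS", "A", 2, 4, 0, 0),
    "END"
  ))
  sites2 <- read_structure(f2, "A")
  m2 <- renumber_sites(sites2, sequence_record("t", "MK"))
  expect_equal(unname(m2), 1:2)

  expect_error(renumber_sites(sites, sequence_record("t", "WWWWWWWWW")),
               "no window")

  renum <- apply_site_numbering(sites, mapping)
  expect_equal(renum$residue_number, 3:7)
})

test_that("contact extraction honors the inclusive distance boundary", {
  near <- structure(data.frame(
    chain = "A", residue_number = 1:2, residue_name = "ALA",
    x = c(0, 7.9), y = 0, z = 0, atom_used = "CB",
    stringsAsFactors = FALSE), class = c("residue_sites", "data.frame"))
  expect_equal(length(contacts_from_structure(near, 8, 1)), 1L)

  far <- near
  far$x[2] <- 8.1
  expect_equal(length(contacts_from_structure(far, 8, 1)), 0L)
})

test_that("a collinear 3.8 A chain has exactly the two near diagonals", {
  n <- 10
  line <- structure(data.frame(
    chain = "A", residue_number = seq_len(n), residue_name = "ALA",
    x = 3.8 * (seq_len(n) - 1), y = 0, z = 0, atom_used = "CB",
    stringsAsFactors = FALSE), class = c("residue_sites", "data.frame"))
  got <- contacts_from_structure(line, 8.0, 1)
  want <- c(paste0(1:(n - 1), "_", 2:n), paste0(1:(n - 2), "_", 3:n))
  expect_setequal(contactr:::pair_key(got$contacts), want)
})

test_that("contact extraction equals the all-pairs oracle on fixture chains", {
  for (spec in list(c(40, 3, 0.7), c(80, 5, 0.4))) {
    ch <- synth_chain(spec[1], seed = spec[2], compactness = spec[3])
    got <- contacts_from_structure(ch$sites, 8, 5)
    want <- brute_structure_contacts(ch$sites, 8, 5)
    expect_equal(as.matrix(got$contacts[, c("res1", "res2")]),
                 want, ignore_attr = TRUE)
  }
})

test_that("site order does not affect the extracted contact set", {
  ch <- synth_chain(30, seed = 9, compactness = 0.8)
  shuffled <- ch$sites[rev(seq_len(nrow(ch$sites))), ]
  a <- contactr:::pair_key(contacts_from_structure(ch$sites, 8, 5)$contacts)
  b <- contactr:::pair_key(contacts_from_structure(shuffled, 8, 5)$contacts)
  expect_setequal(a, b)
})

test_that("evaluate_prediction reproduces constructed compositions", {
  ch <- synth_chain(60, seed = 4, compactness = 0.8)
  ref <- contacts_from_structure(ch$sites, 8, 5)
  expect_gte(length(ref), 20)

  # a prediction equal to the reference is perfect at every factor
  self <- ref
  self$length_hint <- 60L
  ev <- evaluate_prediction(self, ch$sites, factors = c(0.1, 0.5))
  expect_equal(ev$precision, c(1, 1))
  expect_equal(ev$n_selected, ev$n_tp + ev$n_fp + ev$n_unknown)

  # known TP/FP mixture: decoys rank below true pairs, so a small
  # selection is pure and the full selection dilutes exactly
  pred <- synth_prediction(ref, 20, 0.75, seed = 8)
  ev2 <- evaluate_prediction(pred, ch$sites, factors = c(0.1, 1.0))
  expect_equal(ev2$n_selected, c(6L, 20L))
  expect_equal(ev2$precision[1], 1.0)
  expect_equal(ev2$precision[2], 0.75)
  expect_equal(ev2$n_tp[2], 15L)
  expect_equal(ev2$n_fp[2], 5L)

  # disjoint prediction with all residues resolved
  none <- synth_prediction(ref, 10, 0, seed = 8)
  ev3 <- evaluate_prediction(none, ch$sites, factors = 1.0)
  expect_equal(ev3$precision, 0)
})

test_that("decoy dilution never increases precision at a fixed factor", {
  ch <- synth_chain(50, seed = 12, compactness = 0.8)
  ref <- contacts_from_structure(ch$sites, 8, 5)
  base <- synth_prediction(ref, 12, 1.0, seed = 2)
  for (k in c(4, 8)) {
    diluted <- synth_prediction(ref, 12 + k, 12 / (12 + k), seed = 2)
    for (f in c(0.2, 0.5)) {
      p0 <- evaluate_prediction(base, ch$sites, factors = f)$precision
      p1 <- evaluate_prediction(diluted, ch$sites, factors = f)$precision
      expect_lte(p1, p0)
    }
  }
})

test_that("unresolved residues appear as unknowns, not errors", {
  ch <- synth_chain(40, seed = 6, compactness = 0.8)
  ref <- contacts_from_structure(ch$sites, 8, 5)
  pred <- synth_prediction(ref, 10, 1.0, seed = 3)
  # drop half the chain from the structure: pairs touching it become unknown
  partial <- ch$sites[1:20, ]
  ev <- evaluate_prediction(pred, partial, L = 40, factors = 1.0)
  expect_equal(ev$n_selected, ev$n_tp + ev$n_fp + ev$n_unknown)
  expect_gte(ev$n_unknown, 0L)
})
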