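# contactr

Residue–residue contact predictions in R: one data model, seventeen
prediction file dialects, alignment quality statistics, precision
evaluation against protein structures, and publication figures.

## Who this is for

Co-evolution methods (PSICOV, CCMpred, plmDCA, EVfold, Gremlin,
MetaPSICOV, …) predict which residue pairs of a protein are in spatial
contact, and each ships its own text format. Anyone building on those
predictions — structure-prediction pipelines, meta-predictors, model
scoring, benchmark studies — ends up writing the same three things:
format converters, alignment-depth statistics, and a precision
evaluator. `contactr` provides all three as a library plus a small
command-line tool.

## The model in brief

* **Hierarchy.** A `contact` (one scored pair *i < j* with codes, chains,
  distance bounds and match status) lives in a `contact_map` (one
  prediction, optionally with its target sequence and length *L*) inside
  a `contact_file` (one or more maps plus metadata). Sequences mirror
  this as `sequence_record` / `sequence_file`.
* **Precision.** With contacts extracted from a structure at the CASP
  definition (Cβ–Cβ ≤ 8 Å, Cα for glycine), each predicted pair is a
  true positive, a false positive, or *unknown* when a residue is
  unresolved; precision is TP/(TP+FP) over the classified pairs only.
  Predictions are scored on their top ⌊f·L⌋ pairs after a
  sequence-separation filter (|i−j| ≥ 5 by default).
* **Alignment depth.** The number of effective sequences
  N<sub>eff</sub> = Σ<sub>i</sub> 1/|{j : id(i,j) ≥ t}| with t = 0.8 by
  default and identity measured over the full alignment length; plus
  per-column depth, per-sequence coverage, and coverage-based trimming.
* **I/O.** `read_file()` / `write_file()` / `convert_file()` over a
  registry of 17 contact dialects (casprr, psicov, metapsicov, ccmpred,
  evfold, plmdca, freecontact, gremlin, bbcontacts, pconsc, pconsc2,
  pconsc3, epcmap, bclcontact, comsat, mempack, flib) and 4 sequence
  formats (fasta, a3m, stockholm, jones), with lossy fields reported,
  never silently mangled.

## Worked example

Everything below runs on synthetic data from the package's deterministic
generators, so the numbers are reproducible exactly.

```r
library(contactr)

# a 60-residue synthetic globule and its observed contact map
chain     <- synth_chain(60, seed = 4, compactness = 0.8)
reference <- contacts_from_structure(chain$sites,
                                     distance_cutoff = 8, min_separation = 5)
length(reference)
#> [1] 70

# a 20-pair prediction constructed to be 75% correct
prediction <- synth_prediction(reference, 20, tp_fraction = 0.75, seed = 5)
evaluate_prediction(prediction, chain$sites, factors = c(0.1, 0.34))
#>   factor n_selected n_tp n_fp n_unknown precision
#> 1   0.10          6    6    0         0      1.00
#> 2   0.34         20   15    5         0      0.75
```

At factor 0.1 the top ⌊0.1·60⌋ = 6 pairs are selected — all true, so
precision 1.00. At factor 0.34 the whole 20-pair prediction is in play
and precision is exactly the constructed 15/20 = 0.75.

```r
aln <- synth_alignment(30, 50, mutation_rate = 0.25, gap_rate = 0.05, seed = 11)
alignment_stats(aln)
#> <alignment_stats> 30 sequence(s) x 50 column(s)
#>   neff (threshold 0.80): 27.2000
#>   mean coverage: 0.9480

# conversion: any registered dialect to any other of the same kind
write_file(top_n(prediction, 2), format = "casprr")
#> PFRMAT RR
#> MODEL 1
#> 1 14 0 8 1.000000
#> 29 40 0 8 0.975000
#> END
```

The same operations are available from a shell via the installed
launcher (`inst/exec/contactr`): `contactr convert`, `contactr msatool`,
`contactr precision`, and `contactr plot` (contact map, coverage, and
precision-curve figures). Reports are `key: value` lines; exit codes are
0 (ok), 1 (usage), 2 (bad data).

## Package layout

* `R/` — data model (`contact.R`, `contact-map.R`, `containers.R`),
  format registry and dialects (`io-*.R`), alignment statistics
  (`msa.R`), structure evaluation (`structure.R`), figures
  (`visualization.R`), CLI (`cli.R`), fixture generators (`fixtures.R`).
* `tests/testthat/` — unit and property tests with independent
  brute-force oracles for precision, N<sub>eff</sub> and structure
  contacts.
* `vignettes/contact-prediction-toolkit.Rmd` — the methods notes: every
  convention, threshold and numerical choice, with rationale.
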