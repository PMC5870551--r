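---
title: "Working with residue-residue contact predictions"
author: "contactr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working with residue-residue contact predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactr)
```

## The problem

Co-evolution analysis of deep multiple sequence alignments predicts which
residue pairs of a protein are in spatial contact, and those predictions
now routinely guide structure prediction, model scoring and functional-site
discovery. Three practical frictions surround that workflow: every
predictor ships its own text format; judging a prediction requires the
alignment-quality statistics (depth, coverage) that determined its chance
of success; and, when a structure is available, quantifying the prediction
quality requires extracting observed contacts from coordinates and scoring
the prediction against them. `contactr` addresses all three behind one data
model.

## The data model

Contacts live in a three-tier hierarchy. A *contact* is one scored residue
pair `(i, j)` with optional residue codes, chain labels, distance bounds
and a match status. A *contact map* is the ordered collection of contacts
belonging to one prediction, optionally carrying the target sequence or an
explicit target length L. A *contact file* holds one or more maps plus
file-level metadata (the CASP RR format, for instance, can store several
MODEL blocks per file). Sequences mirror this with two tiers: a *sequence
record* inside a *sequence file*, the latter flagged as an alignment when
rectangular.

Contacts are held canonically as `res1 < res2`; self-pairs are rejected at
construction rather than silently dropped, because they only ever arise
from malformed input. Duplicate pairs are resolved by keeping the first
occurrence (with a warning): prediction files are conventionally sorted by
score, so the first occurrence is the highest-ranked one. Ties between
equal scores are broken by ascending `(res1, res2)` so that every ordering
operation is deterministic across platforms.

## Precision against a structure

The central analysis is the precision of a prediction judged against the
contacts observed in a structure. The contact definition follows the CASP
convention: two residues are in contact when their C-beta atoms
(C-alpha for glycine, or when C-beta is missing) lie within 8.0 Å,
boundary inclusive. Both the cutoff and the atom rule are arguments.
Extraction is deterministic for ensemble files: first MODEL only, and
alternate locations resolved by highest occupancy with alphabetic
tie-break.

`match_contacts()` classifies each predicted pair as a true positive (the
pair exists in the reference), a false positive (both residues are
resolved in the structure but the pair is absent), or *unknown* (either
residue is unresolved). Precision is `TP / (TP + FP)`; unknown contacts are
excluded from numerator and denominator because an unevaluable contact is
not evidence of error. The two maps must share one numbering frame:
`renumber_sites()` finds the exact sequence window matching the structure's
residues (or fails asking for a manual offset via `renumber_contacts()`) —
no silent re-alignment is attempted, since that is where registration bugs
hide.

Predictions are conventionally scored on their top `f * L` pairs,
`floor`-rounded to a whole number of contacts. `evaluate_prediction()`
applies a sequence-separation filter of `|i - j| >= 5` (the community
default; configurable) to *both* the prediction and the structure map so
the comparison is like-for-like, then reports counts and precision per
factor. A factor at which nothing can be classified yields `NA` — a gap in
the curve, not an exception, so multi-factor sweeps always complete.
"Long-range" operations default to a separation of 23.

```{r precision-example}
chain <- synth_chain(60, seed = 4, compactness = 0.8)
reference <- contacts_from_structure(chain$sites, 8, 5)
prediction <- synth_prediction(reference, 20, tp_fraction = 0.75, seed = 5)
evaluate_prediction(prediction, chain$sites, factors = c(0.1, 0.34))
```

## Alignment statistics

The usefulness of a co-evolution prediction rises with the
redundancy-corrected depth of its alignment, the *number of effective
sequences*:

$$N_{\mathrm{eff}} = \sum_i \frac{1}{\left|\{\, j : \mathrm{id}(i,j) \ge t \,\}\right|}$$

Pairwise identity here uses the full alignment length as denominator, so
gap positions count against identity; this is the conservative convention
for redundancy weighting and makes the measure symmetric and unambiguous.
The threshold defaults to `t = 0.8`, the common choice in co-evolution
reweighting pipelines. Each sequence counts as its own neighbor
unconditionally — with the full-length denominator a gap-rich sequence can
otherwise fall below the threshold against *itself*, and the unconditional
self-neighbor keeps every neighborhood non-empty and
`1 <= Neff <= N`. Identities are computed exactly for all `N^2` pairs;
inputs here are desk-scale and correctness beats approximation.

Coverage comes in two views — per sequence (non-gap fraction) and per
column (number of non-gap sequences) — connected by a conservation
identity (both sum to the total non-gap character count).
`trim_by_coverage()` first drops low-coverage sequences, then low-depth
columns, in that order; the first sequence is treated as the query and is
never dropped, because downstream contact indices refer to it.

## File formats

Seventeen contact dialects and four sequence formats register a reader, a
writer, and a declaration of which fields of the data model they can
carry. `read_file()`, `write_file()` and `convert_file()` are the only
entry points; `restrict_to_representable()` previews exactly what a lossy
conversion will drop. Scores are written as fixed-point with six decimals,
which round-trips exactly without scientific-notation surprises. Decimal
commas are rejected: parsing is locale-independent by construction.

Dialect-specific decisions worth knowing:

* **CCMpred** matrices are symmetric by construction; on read the upper
  triangle wins and an asymmetry beyond `1e-6` raises a warning (corrupt
  files should be noticed, not normalized silently). Only non-zero cells
  become contacts — in a dense matrix a zero coupling is
  indistinguishable from an absent pair. Writing needs a known L (a
  sequence or `length_hint`).
* **A3M** lowercase insert states are kept verbatim by default;
  `strip_inserts = TRUE` removes them to recover a rectangular alignment.
  Both behaviours are needed: verbatim for storage, stripped for
  analysis.
* **Stockholm** per-column annotations (`#=GC` and friends) are preserved
  as opaque remarks on read and never regenerated on write; mangling
  annotations would be worse than dropping them.
* Gap characters `-` and `.` are both accepted and normalized to `-`.
* **COMSAT** carries no score; contacts read from it get `raw_score = 1`.

Format detection (`sniff_format()`) only answers when a structural
signature is decisive (`PFRMAT RR`, `# STOCKHOLM`, `>` records, a square
symmetric numeric matrix); the five-column layouts shared by several
dialects return `"unknown"` rather than a guess, and the command-line
tools then require an explicit `--informat`.

## Figures

Three generators cover the standard plots: the mirrored contact-map
scatter (status-colored when a reference is supplied), per-column
alignment depth, and precision versus L-factor. Every generator writes
PNG/SVG/PDF *and* returns a manifest of exactly the points drawn; all
numeric testing runs against manifests, never pixels, and manifests are
invariant to rendering-only parameters (dpi, size). Every plotted series
is mirrored across the diagonal — including second maps and references,
which are distinguished by color — so the manifest size is always twice
the number of contacts per series. The coverage figure interprets its
y-quantity as per-column non-gap depth (the natural reading for judging
co-evolution input quality) and draws guide lines at depths of 1x and 5x
the alignment length when they fall within range, as quick
depth-adequacy marks.

## Synthetic fixtures

Every analysis is testable without downloads via three generators, all
driven by a portable Park-Miller linear congruential stream
(`portable_rng()`) rather than R's global generator, so identical seeds
give byte-identical fixtures on every platform (all intermediates stay
below 2^53 and are exact in doubles).

* `synth_chain()` grows a self-avoiding walk with a fixed 3.8 Å step (the
  C-alpha virtual bond length). A pull toward the origin engages once the
  walk leaves a sphere of radius `step * length^(1/3)` — roughly the
  smallest ball that can hold the chain at physical density — with
  strength `compactness`. Near 0 the chain stays essentially straight and
  has no long-range contacts; near 1 it collapses into a globule with
  many. Clashes are rejected at 0.9 step lengths with bounded retries.
* `synth_prediction()` *constructs* its true/false composition exactly
  (round-half-up of `tp_fraction * n`) instead of sampling it, so
  evaluation results on fixtures are exact identities, not statistical
  expectations. True pairs receive the top scores; decoys rank strictly
  below. Both pools are restricted to separations of at least 5 by
  default so the composition survives the evaluation filter.
* `synth_alignment()` mutates an ancestor per position independently; the
  ungapped ancestor is kept as the first (query) sequence.

What these fixtures do *not* emulate: real secondary structure, realistic
contact-density scaling, co-evolving column statistics, or the indexing
pathologies of real PDB entries (insertion codes, negative author
numbers). Green tests therefore certify the bookkeeping and the
arithmetic — classification, counting, selection, conversion — not
biological realism of inputs.

## Numerical choices

* `select_by_l_factor()` computes `floor(f * L + 1e-9)`: the guard
  absorbs binary representation error (`0.7 * 10` is `6.999...` in
  doubles and must select 7 contacts, not 6) without changing the floor
  of any genuinely fractional product.
* `rescale_scores()` on a constant map sets every scaled score to 0 with
  a warning: any constant is arbitrary, and 0 signals "no discriminative
  information".
* Neff thresholds compare with a `1e-12` tolerance so identities that are
  exact fractions are not lost to rounding.
* Distance boundaries are inclusive (`<= 8.0` Å), matching the usual
  statement of the contact definition and the brute-force oracles in the
  test suite.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
chains up to 200 residues, alignments up to 50 sequences by 60 columns,
50 randomized round-trip objects per format, and 200 randomized
precision triples. These sizes exercise every code path while keeping
the whole suite in the half-minute range on a single core.

## Limitations

* PDB ATOM records only; mmCIF, insertion codes and hetero atoms are out
  of scope, as is inter-chain contact bookkeeping beyond the stored chain
  labels.
* No distance-bin (distogram) representations and no meta-prediction or
  re-ranking of contacts.
* The structure-to-sequence mapping requires an exact identity window; a
  mutated or engineered construct needs a manual offset.
* The 17-dialect registry targets the classic co-evolution ecosystem;
  adding a dialect means registering a reader/writer pair, which the
  registry design keeps deliberately small.
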