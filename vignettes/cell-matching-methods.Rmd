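---
title: "Unit-cell matching: method, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unit-cell matching: method, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmatch)
```

## The problem

When a protein crystal is characterized at a synchrotron beamline, the unit
cell and (often) the space group are known within minutes, long before any
structure is solved. If a crystal with an equivalent lattice has already
been deposited, knowing that immediately is valuable: it can reveal that a
"new" crystal is actually a known contaminant or byproduct of the
expression host, or point at a homologous structure worth trying for
molecular replacement. `cellmatch` answers the question *"which deposited
entries have essentially this lattice, and what protein content do they
hold?"* from cell dimensions alone — deliberately fast and inclusive rather
than selective; confirming a match is left to downstream structure-factor
methods.

The pipeline has three stages:

1. **Reduction** — canonicalize the query cell and every database cell to a
   Niggli-reduced primitive (P1) cell.
2. **Superposition** — compare reduced cells by least-squares superposition
   of their four vertex points over all six right-handed axis assignments;
   keep entries within a cutoff.
3. **Family grouping** — cluster the hits' chain sequences and merge hits
   whose symmetry-scaled cluster content is identical, so each distinct
   crystal form is reported once.

## Reduction to a canonical primitive cell

A lattice has infinitely many valid cell descriptions. Deposited entries
use conventional settings — possibly centered (A, B, C, I, F, or the
hexagonal setting of rhombohedral lattices) — so identical lattices can
carry very different-looking cell parameters. Two steps remove this freedom:

* **Centering removal.** A fixed conventional-to-primitive transformation
  per centering type (International Tables conventions) maps the
  conventional basis to a primitive one; the volume shrinks by the
  centering multiplicity (2 for A/B/C/I, 3 for the hexagonal rhombohedral
  setting, 4 for F). The specific matrix chosen per type is immaterial
  because of the next step.
* **Niggli reduction** (Křivý–Gruber iteration on the metric tensor). The
  Niggli cell is a unique canonical description of a lattice, so the query
  and every database entry become directly comparable. The iteration uses
  comparisons stabilized by $\varepsilon = 10^{-5} \times$ the mean squared
  cell edge, *recomputed each iteration from the current cell*: the mean
  squared edge shrinks as the basis shortens, so two different descriptions
  of one lattice terminate in the same reduced form (a fixed
  $\varepsilon$ taken from a wildly oblique starting description can mask a
  reduction step near termination). The sign-normalization step of the
  iteration uses the *actual* signs of the off-diagonal metric elements,
  never $\varepsilon$-classified ones — forcing a sign onto a merely
  near-zero element is not an exact change of basis and would perturb the
  lattice by up to $\varepsilon$. With these two numerical choices the
  reduction is, in our property tests, invariant under random unimodular
  re-descriptions of the lattice across thousands of cells. A
  1000-iteration cap guards against pathological input. Residual flips at
  exact degeneracies (e.g. two lattice vectors of identical length) are
  harmless: the superposition stage tries all six axis assignments anyway.

Space-group symbols are resolved against an embedded table of the 65
Sohncke groups — the only groups available to enantiopure macromolecules —
with spacing-insensitive matching, common short forms (`C2`, `P21`,
`H3`), rhombohedral setting suffixes (`:H`, `:R`), and a user-extensible
alias table for curated alternate symbols. A bare rhombohedral symbol like
`R3` defaults to the hexagonal setting and the report flags the
assumption. A missing symbol means P1: a cell with no claimed symmetry is
still a valid query, it is simply only Niggli-reduced.

## Superposition score

Two reduced cells are compared as rigid bodies. Each cell is represented by
four labelled points — the origin `O` and the three axis endpoints `A`,
`B`, `C` of its orthogonalized basis — and superposed by the Kabsch
algorithm: centroids aligned, optimal rotation from the SVD of the
covariance matrix with the determinant-sign correction, so the rotation is
always proper. Reflections are never allowed; protein crystals are
enantiomorphic, and a mirror-image lattice is *not* the same crystal form.

Because the labelling of axes is a convention, the candidate cell is tried
in all $3! = 6$ joint permutations of its (length, opposite-angle) pairs,
each re-orthogonalized right-handedly; the reported r.m.s. difference is
the smallest of the six fits. Ties prefer the identity assignment, then
lexicographic order, making results exactly reproducible. The score is
symmetric in query and candidate and invariant under axis relabelling of
either side (property-tested), and agrees with a quaternion-parameterized
brute-force rotation search to $10^{-4}$ Å on random point sets.

A candidate is a **hit** when its best r.m.s. difference is within the
cutoff: by default the larger of **2.5 Å** or **1% of the sum of the
longest and shortest query-cell dimensions**. The percentage term uses the
query cell *as supplied* (not its reduced form) — the natural reading of
the rule, flagged here because the alternative is defensible; for typical
protein cells the two differ little, and the cutoff can always be set
explicitly. Hits are sorted by r.m.s. difference with entry-id tie-breaks,
so output is independent of scan order and of any parallel partitioning a
caller might add.

## Family grouping

A popular protein can have dozens of isomorphous depositions; reporting
each one separately drowns the informative matches. Hits are therefore
grouped by *content*:

1. All chains of all hits are clustered greedily at 90% sequence identity
   (default), CD-HIT style: sequences sorted by length descending (ties
   broken lexicographically, then by entry/chain id), each sequence joins
   the first cluster whose representative it matches at or above the
   threshold, else founds a new cluster. Identity is the number of
   identical positions in an optimal global alignment divided by the
   *shorter* sequence length. The alignment (match +1, mismatch 0, affine
   gap open 10 / extend 0.5 — gap costs only shape the alignment) is exact
   rather than word-filtered: at hit-set scale (tens to hundreds of
   sequences) exactness and determinism are worth far more than CD-HIT's
   heuristic speed.
2. Each hit's asymmetric-unit content — chains per cluster — is multiplied
   by the **primitive** symmetry-operator count of its space group
   (conventional operator count divided by centering multiplicity). The
   stored P1 cell is the *primitive* cell, so its content is ASU content
   times the primitive count; using the conventional count would wrongly
   split the same crystal form deposited in centered versus primitive
   settings into different families. Only polymer chains present in the
   entry's chain list are counted.
3. Hits with identical cluster-multiplicity vectors form one family,
   represented by the member with the smallest r.m.s. difference (ties by
   entry id), families sorted by representative r.m.s. difference.

Clustering is recomputed per query over the hit set only — cluster ids are
meaningful within one report, not globally.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| match cutoff | max(2.5, 1% of (max+min) query edge) | Å | separates isomorphous lattices from coincidental similarity; scales with cell size |
| identity threshold | 0.90 | fraction of shorter length | tight enough to separate homolog families, loose enough to absorb point mutants and tags |
| Niggli $\varepsilon$ | $10^{-5}\times$ mean squared edge | Å² | comparison stabilizer; see above |
| validity floor $v^2$ | $10^{-12}$ | — | rejects numerically degenerate cells before any linear algebra |
| iteration cap | 1000 | steps | pathological-input guard; never reached for realizable cells |

## The synthetic generator

`build_fixture_db()` emulates a PDB-like metadata dump with known ground
truth. Its defaults are the study conditions used throughout the tests:
3 planted match groups and 30 decoys across eight common Sohncke space
groups (P1, P21, C2, P212121, P41212, P321, R3, I23), cell
edges 30–150 Å, within-group jitter of 0.05 Å / 0.05° on the free
parameters of the crystal system, 120-residue chains, 1–2 chains per ASU,
and 95% intra-family sequence identity (unrelated random sequences sit
near the ~6% identity floor). Cells are drawn *consistent with their
space-group's metric constraints* (tetragonal a=b, right angles, and so
on), as real depositions are. Perturbed copies are accepted only if their
reduced-cell r.m.s. difference to the parent is below 45% of the parent's
default cutoff, decoys only if beyond twice every parent's cutoff — so the
planted hit sets are recoverable exactly, by construction, and a recovery
failure in tests indicates a real defect rather than sampling noise.
Everything is deterministic in the seed, down to byte-identical files.

What the generator does **not** emulate: indexing-convention quirks and
curated alternate symbols beyond the alias mechanism, non-Sohncke entries
(the table simply rejects them), heteroatom/nucleic-acid content,
realistic organism names or R-factor distributions, and the sheer scale
and redundancy of the real archive. Passing the ground-truth tests
therefore demonstrates the correctness of the reduction/superposition/
grouping logic, not retrieval performance against the live PDB.

## Problem sizes in the shipped tests

The test-suite sizes were chosen to exercise every code path at desk
scale: 1000-cell property runs for the reduction invariants, 200 random
point-set pairs against the rotation-search oracle, 25 lattices against a
brute-force successive-minima enumeration, 150 random pairs against the
exhaustive alignment oracle, and end-to-end ground-truth recovery on five
fixture seeds of ~45 entries each. Fixture databases are generated in
memory at test time; nothing binary ships with the package.

## Known limitations

* The reduction canonicalizes with Niggli reduction on **both** the query
  and the database side. A tool that stores merely primitive (not
  Niggli-reduced) cells would report identical matches but different
  intermediate cell values.
* mmCIF ingest reads header categories (cell, symmetry, method, R factors,
  source organism, polymer sequence loop) with a deliberately minimal
  parser; deeply nested or exotic CIF constructs are out of scope — the
  TSV bulk format is the robust ingestion path.
* Identity clustering is exact-alignment based; for thousands of hit
  chains a word-filtered pre-screen would be the natural optimization.
* Matching is by lattice geometry alone. Similar cells do not imply
  similar structures; the family report tells the user what content the
  matching lattices hold, not that the query crystal contains it.
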