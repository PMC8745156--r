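---
title: "Structural annotation of MTHFR deficiency variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural annotation of MTHFR deficiency variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mthfrvar)
```

Human methylenetetrahydrofolate reductase (MTHFR) is a homodimeric enzyme
with a FAD-dependent catalytic domain and a SAM/SAH-binding regulatory
domain connected by a linker. Missense variants that lower its activity
produce MTHFR deficiency. This vignette explains what each layer of the
package computes, why the defaults are what they are, and where the design
was genuinely open.

## The variant table and its quirks

`parse_variant_table()` reads a TSV with one row per missense variant:
wild-type residue, position (UniProt P42898 numbering), mutant residue,
domain, free-text effect, three per-method ΔΔG predictions (kcal/mol), an
interaction-site flag and an integer RSA percent. The packaged table
(`mthfr_table1_path()`) is a faithful transcription of the published
72-row annotation: it preserves a duplicated M338T row exactly as
printed, and `deduplicate_variants()` removes duplicates (key: wild-type,
position, mutant; first occurrence kept) before any statistics are
computed. The published narrative variously counts 72 or 71 variants and
41/42 catalytic versus 30/31 regulatory; the package reports both the raw
row counts and the unique counts as diagnostics instead of silently
correcting either. The domain boundary is fixed at 335/336 — the table's
own section split, consistent with the regulatory model region starting
at 336.

```{r}
report <- run_table_analysis(mthfr_table1_path())
report
```

## Consensus destabilization

The sign convention is ΔΔG = ΔG~wt~ − ΔG~mut~: negative values mean the
mutant is less stable. A variant is called destabilizing when at least
`min_votes = 2` of the three predictions are at or below
`threshold = −1` kcal/mol. Two deliberate choices:

* **The threshold is inclusive.** The source material states the rule
  both as "≤ −1" and as "lower than −1"; only the inclusive reading
  reproduces the printed destabilizing set (V253F carries a printed −1
  entry and is marked destabilizing), so ≤ is adopted and pinned by a
  test.
* **Votes are unweighted and never averaged.** The three predictors have
  very different error profiles; a vote count is robust to a single
  outlier (e.g. the −16.08 kcal/mol FoldX value at C130R), whereas a mean
  is not.

The 1 kcal/mol magnitude reflects the typical spread of the experimental
thermodynamic data such predictors are trained on. For positions where
the crystal carries the mutant residue (position 429 in the 6FCX
structure), `reverse_variant()` negates the triplet computed for the
reverse substitution — an involution, tested as such.

## Solvent accessibility and interfaces

`shrake_rupley()` computes per-atom accessible surface area as
4π(r + w)² × (accessible points / n): each atom's van der Waals sphere is
expanded by the probe radius w, n test points are placed on it with a
deterministic golden-section spiral, and a point is accessible iff it
lies outside every other atom's expanded sphere. Defaults: w = 1.4 Å (a
water probe), n = 960 points. At 960 points a single-sphere area is exact
by construction and the total area of a small peptide moves by less than
0.5% when n doubles; the unit tests hold the implementation to an
independent 10⁶-point latitude–longitude quadrature within 1% on
overlapping spheres.

Numerical choices worth stating:

* **Orientation convention.** The quadrature is evaluated in a canonical
  frame (centered, principal axes, axis signs fixed by coordinate
  skewness, right-handed), so ASA is invariant under rigid motion of the
  input to within 1e-6 — useful for regression tests and for comparing
  structures superposed by different tools. For highly symmetric point
  sets the principal frame is ambiguous, but such inputs (isolated
  spheres, shells) have orientation-independent ASA anyway.
* **Blocking test.** A point exactly on a neighbour's expanded sphere
  counts as accessible (strict inequality); the choice only matters for
  engineered tangent configurations.
* **Neighbor search.** A uniform-grid cell list culls candidate pairs;
  a property test asserts byte-identical results against the quadratic
  all-pairs reference.
* **Atom selection.** Hydrogens and waters are always dropped; other
  heteroatoms (FAD, SAH) are dropped by default because the packaged RSA
  values — several 0% residues inside cofactor sites — are protein-only
  surfaces. Alternate locations resolve to highest occupancy, ties to
  the lowest altloc letter. Residue numbering is taken verbatim from the
  file and assumed to match UniProt positions; no alignment-based
  renumbering is attempted.

Relative accessibility divides residue ASA by a residue-type maximum.
The bundled table is the Gly-X-Gly *theoretical* maximum set of Tien et
al. (2013); the normalization table is a configuration item because
published RSA values rarely state which maximum set they used, and
integer-rounded RSA of exposed residues can differ by a few percent
between reasonable choices. Exposure uses an inclusive 20% threshold:
with the packaged table's RSA values this reproduces the catalytic
domain's 14 exposed non-interaction variants, while no single threshold
reproduces every narrative count for the regulatory domain — hence the
threshold is exposed as a parameter rather than hard-coded.

`interface_residues()` declares a residue part of an interface when its
ASA drops by at least 1 Å² in the complex versus the isolated component,
both computed with identical quadrature settings. Van der Waals radii
default to C 1.76, N 1.65, O 1.40, S 1.85 Å and are configurable.

The reference analysis of the full MTHFR homodimer (PDB 6FCX, chains
A/B) is expressed in the test suite but requires the user to supply the
coordinate file; the package does not redistribute or download it. All
structure-layer behaviour is therefore certified on analytic and
synthetic geometry, which verifies the algorithm, not its agreement with
any particular deposited structure.

## Variation-type fingerprints and the chi-square

Substitutions are typed by ordered class pairs over apolar
{G,A,V,I,L,P,M}, polar {S,T,C,N,Q,H}, aromatic {F,W,Y}, charged
{D,E,K,R}; the four sets partition the 20-letter alphabet (asserted at
load). Distinct substitutions at one position (R46Q, R46W) count
separately. `chi_square_pseudocount()` compares two 16-cell count
vectors as a 2×16 homogeneity table with 0.5 added to every cell
(df = 15, Pearson, no continuity correction) — the simplest symmetric
construction consistent with pseudocount regularization, and
swap-invariant by design. A goodness-of-fit variant (one domain's counts
against the other's frequencies) was considered and rejected because it
is direction-dependent.

On the packaged table this test does **not** reach the 10% significance
level (the acceptance script prints the computed p-value, about 0.88).
With 41 and 30 observations spread over 16 sparse cells that is
unsurprising; a fingerprint difference of this size is only detectable
against a much larger background sample. The package therefore also
exposes `background_matrix()` — a seeded multinomial sampler emulating a
large pathogenic-variant background (default n = 22,763), or explicit
frequencies from a TSV — so each domain can be compared against a
high-count background, where the homogeneity test has power. The
direct catalytic-versus-regulatory comparison is reported as computed
rather than forced to a foregone conclusion.

## The domain profile model

`build_profile()` estimates a light profile from an alignment: match
columns are those with gap fraction ≤ 0.5; emissions are
(count + 1)/(total + 20) per match column (Laplace pseudocounts);
transitions over {M→M, M→D, M→I} (and the D-source counterparts) are
counted per consecutive match-column pair, a traversal of intervening
insert columns counting as →I. No Dirichlet mixtures, no sequence
weighting, no scoring or database search: the model exists to place
variants on a column architecture, and the minimal estimator is
checkable by hand (a 3×4 alignment with hand-computed parameters is
frozen in the tests). The regulatory model region spans human positions
336–566 — the whole span including the linker — and
`map_variants_to_architecture()` projects variants into it via the
reference row, representing the catalytic domain by its 1–335 span.

## Synthetic data: what it does and does not show

The generators make every stage testable offline:

* `make_toy_structure()` — idealized single atoms, an alanine, a
  tripeptide with documented bond lengths, and a closed shell that fully
  buries its central atom (analytic/oracle surface areas).
* `make_toy_dimer()` — two tripeptides translated by a contact offset;
  at the documented 6 Å contact every residue pair loses area, at 50 Å
  the interface is empty; chains are exact mirrors.
* `simulate_variant_table()` — ΔΔG triplets drawn from N(−2, 0.5) for
  destabilizing and N(0, 0.5) for neutral variants, rejection-sampled so
  the consensus rule recovers the ground-truth labels exactly. These
  distributions are a separability device, not thermodynamics: recovery
  tests certify the classifier's logic, not predictive accuracy on real
  proteins. Default sizes: 100 variants, half destabilizing, domain
  split 41/72 as in the packaged table.
* `simulate_msa()` — a regulatory-like alignment (default 50 sequences
  over positions 336–566, 10% substitutions, 5% deletions, a gappy
  insert block) for profile construction; it models no real phylogeny.

All generators are pure functions of their seed. What passing tests on
synthetic data do *not* show: agreement of computed RSA with any
particular experimental structure, realism of simulated ΔΔG values, or
evolutionary plausibility of simulated alignments.

## Problem sizes and runtime

The default test and acceptance runs use desk-scale inputs: the 72-row
table, toy structures of ≤ 61 atoms, 100-variant simulations, a
50 × 234 alignment, and a 10⁶-point quadrature oracle on two atoms.
Everything completes in seconds on one CPU; a full ~10,000-atom dimer
analysis at 960 points per atom takes minutes.

## Known limitations

* Shrake–Rupley quadrature, not Lee–Richards slicing or DSSP; integer
  RSA values of exposed residues may differ by a few percent from
  DSSP-derived publications even with the same maximum-ASA table.
* No hydrogen placement, no secondary-structure assignment.
* The ΔΔG predictors themselves are out of scope; their printed outputs
  are inputs.
* The profile model does not score sequences (no forward/Viterbi,
  no E-values).
* Interaction-site flags are consumed as given, not predicted.
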