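---
title: "Methods: the QTY code analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the QTY code analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtykit)
```

# The problem

Integral membrane proteins expose hydrophobic side chains — predominantly
leucine, isoleucine, valine and phenylalanine — on the lipid-facing surface
of their transmembrane (TM) α-helices. Out of the bilayer they aggregate
unless detergent-solubilised. The QTY code is a minimal design rule for
water-soluble variants: within annotated TM spans substitute L→Q, I→T, V→T
and F→Y, exploiting the close steric match between each pair (the polar
partner differs mainly by an amide or hydroxyl where the native residue has
saturated carbon). `qtykit` implements the rule and the sequence-, structure-
and surface-level quantities used to judge its consequences.

# The substitution model

`qty_transform()` applies the fixed four-pair mapping strictly inside the TM
spans of a topology (1-based inclusive intervals, UniProt convention,
validated to be sorted and non-overlapping). Three properties follow by
construction and are enforced as tests:

* **Locality** — positions outside spans are untouched, including L/I/V/F
  residues there.
* **Idempotence** — a variant contains no substitutable residue inside the
  spans, so transforming it again is the identity.
* **Deterministic accounting** — the substitution list enumerates each
  change; variation percentages equal brute-force position counts.

The TM variation denominator is the residue count inside the spans of the
*native* annotation. The alternative (spans re-derived on the variant) is
identical here because the transform never changes span boundaries; we fix
the native convention so the statistic stays meaningful if gapped
correspondences are ever added.

Percentages, pI and molecular weight are reported to 2 decimals, the
precision customary in the field's comparison tables; the underlying
functions (`isoelectric_point()`, `molecular_weight()`, `gravy()`) return
full precision.

# Sequence metrics

**Isoelectric point.** The net charge at a given pH is the
Henderson–Hasselbalch sum over ionizable groups, with the N-terminus, H, K, R
positive and the C-terminus, D, E, C, Y negative. We use the Bjellqvist pKa
set (the one behind the common web calculators): residue-specific N-terminal
pKa with a generic 7.5 fallback, C-terminus 3.55, side chains D 4.05, E 4.45,
C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0. The table is an argument
(`bjellqvist_pka()`), so the model is swappable. Z(pH) is strictly
decreasing, so the unique root on [0, 14] is found by bisection to
|Z| < 1e−4 or an interval below 1e−4 pH units; the test suite checks the
solver against an independent dense-grid scan of the same curve at 1e−4
resolution.

Because Q, T and Y-free substitutions leave every ionizable group untouched,
a transform with no F→Y substitution preserves the pI *exactly* — a stronger
statement than "similar", and asserted bit-for-bit in the tests. One corner
case: if residue 1 itself is substituted I→T or V→T, the residue-specific
N-terminal pKa changes (7.5/7.44 → 6.82) and the equality can break. The
synthetic generator always places a loop before the first helix, so the
invariant holds under all generated conditions; for user data with a TM span
at position 1 the pI is still computed correctly, only the exact-equality
shortcut does not apply.

**Molecular weight** is the sum of average (not monoisotopic) residue masses
plus one water (18.015 Da), matching the convention of web MW tools. Each
substitution then shifts the mass by a fixed delta: L→Q +14.97, I→T −12.05,
V→T +1.97, F→Y +16.00 Da (one average oxygen). Note the sign of I→T: whether
a variant is heavier than its native protein depends on composition, so no
direction is asserted as an invariant.

**GRAVY** is the mean Kyte–Doolittle hydropathy. All four substitutions
strictly decrease the per-residue value, so any transformed TM segment
strictly decreases its GRAVY — the sequence-level counterpart of losing the
hydrophobic surface.

# Structure comparison

Structures are read from fixed-column PDB or mmCIF (via bio3d) into a tidy
atom table. Selection rules: polymer ATOM records only, waters and HETATM
excluded by default, first model of multi-model files, and one conformer per
altloc group (highest occupancy, ties to the alphabetically first id). For
mmCIF the author (`auth_`) chain and residue numbering is used, because it
matches PDB-format numbering and UniProt-aligned TM annotations.

**Correspondence.** Residues pair by shared (residue number, insertion code)
restricted to residues with a C-alpha in both models (`by_resnum`), which
reproduces the loop trimming real comparisons need: residues unresolved in
either model simply drop out. `by_position` (i-th CA with i-th CA) exists
for models with incompatible numbering. Gapped, sequence-alignment-based
correspondence is out of scope.

**Kabsch fit.** The optimal proper rotation minimising the paired squared
error is the closed-form SVD solution with the reflection corrected by
flipping the smallest singular vector, so det(R) = +1 always, including
mirrored and near-planar inputs (both tested). Collinear point sets are
rejected (the second singular value below 1e−12 of the first). The fit uses
C-alpha atoms only: QTY substitution changes side chains by design, so CA is
the comparison the scientific question wants; it is also robust to differing
side-chain completeness between experimental and predicted models.

**Refinement.** Interactive tools report RMSDs after discarding badly
fitting pairs. We emulate this transparently: fit all pairs (reported as
`rmsd_all`), then up to `cycles` rounds of "discard pairs with post-fit
distance > `reject_factor` × current RMSD, refit" (`rmsd_refined`), stopping
early when nothing is discarded or fewer than 3 pairs would remain. Defaults
`cycles = 5`, `reject_factor = 2.0` are conventional; both are arguments
everywhere, since published RMSDs rarely state their rejection settings —
which is also why external RMSDs are reproduction targets with tolerance,
not bit-exact references. The retained-pair RMSD is non-increasing across
cycles, and the full cycle log is kept on the result object.

TM-domain-only comparisons (`tm_only = TRUE`) cut both models down to
residues inside the TM spans before correspondence, mirroring how
whole-protein similarity can mask — or be masked by — divergent soluble
domains.

# Surface analysis

`shrake_rupley_sasa()` estimates solvent-accessible surface area by point
sampling: each atom's sphere is expanded by the probe radius (default 1.4 Å,
a water molecule) and covered with `n_points` test points; points inside no
other expanded sphere are accessible, and the accessible fraction times
4π(r+probe)² is the atom's area. Radii: C 1.70, N 1.55, O 1.52, S 1.80 Å,
default 1.70 Å for unlisted elements; hydrogens are ignored. The point set
is a deterministic golden spiral, so results are seed-free and exactly
reproducible; 960 points give sub-1 % convergence against 4000 (tested), and
the implementation is validated against the closed-form isolated sphere, the
analytic two-intersecting-spheres area, and an independent
latitude–longitude quadrature on small toys. The neighbour search is
cutoff-limited (only atoms within the sum of expanded radii can occlude), a
pure optimisation that cannot change the result.

The **hydrophobic surface fraction** — SASA on residues in
{A, V, L, I, P, F, M, W} (Kyte–Doolittle-positive plus A/P/W by convention,
configurable) divided by total SASA — is this package's numeric
operationalisation of the "hydrophobic patch" comparison usually made by
eye on coloured surface renderings; reports label it as such. For
before/after comparisons we use a **relabel-only surrogate**: the variant
reuses the native coordinates with residue names remapped by the QTY rule.
This encodes the design premise that QTY variants keep the native fold,
removes any dependence on structure prediction, and makes the comparison
exact: total area is unchanged, so the fraction strictly decreases whenever
any substituted residue is solvent-exposed.

# The synthetic generator

`bundle_spec()` + `generate_membrane_protein()` + `generate_bundle_structure()`
emulate what the pipeline consumes in a real study: a multi-pass membrane
protein with hydrophobic-enriched helices and polar loops, plus consistent
3D coordinates. Defaults: 6 helices (real TM domains carry 5–11; the
generator accepts 2–12) of 22 residues — the bilayer span at 1.5 Å rise per
residue — joined by 6-residue loops. The TM composition is L/I/V/F-heavy
(58 % substitutable residues in expectation, chosen to put TM variation in
the ~50 % regime typical of QTY designs); loops draw from a polar
composition. Coordinates are ideal α-helices (rise 1.5 Å, twist 100°/residue,
CA radius 2.3 Å, giving the canonical 3.83 Å CA–CA chord) with axes on a
circle at 10 Å spacing, alternating up/down as in an antiparallel bundle.

Loop residues are deliberately **omitted** from the coordinates — unresolved,
like unstructured loops in cryo-EM models — so that `by_resnum`
correspondence against the full-length annotation exercises exactly the
trimming logic real comparisons rely on. `perturb_structure()` adds
per-coordinate Gaussian noise and a known rigid motion, giving matched pairs
with ground truth: for σ noise on n pairs the fitted RMSD concentrates
around σ√3·√(1 − 6/(3n)) (six degrees of freedom absorbed by the fit), the
basis of the 50-seed recovery benchmark.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: no physical packing or energetics, no side
chains, no loops in 3D, no correlated (domain-level) deformations between
native and variant structures, no helix kinks or tilts. Results on real
structure pairs additionally depend on the annotation source for TM spans
and on the rejection settings behind published RMSDs, so agreement there is
expected only within tolerance.

# Pipeline and reproducibility

`run_report()` maps a manifest (id, FASTA, topology, optional structure
pairs) to one row per protein with the full metric set and whole-chain plus
TM-only RMSDs; failures are isolated per entry with the message in an
`error` column, so one bad structure cannot abort a batch. Reports are
deterministic given inputs and seeds, with a fixed documented schema.

`scripts/acceptance.R` regenerates the package's headline numbers from
scratch at desk scale: a six-protein study (5–10 helices, helix length 22,
loop length 6, σ = 0.5 Å variant noise), a 50-seed RMSD-recovery benchmark
on a 200-residue bundle, and the hydrophobic-fraction comparison — sizes
chosen so the whole run finishes in well under a minute while keeping the
Monte-Carlo standard error of the recovery benchmark below 0.005 Å. All
randomness derives from the `--seed` argument.

# Known limitations

* The substitution code is fixed; user-defined mappings are out of scope.
* No TM-span prediction: spans are inputs, and reproducing any published
  variation percentage exactly depends on which annotation the original
  analysis used.
* No gapped correspondence, multi-model ensemble fitting, or secondary
  structure assignment.
* SASA is accessible-surface only (no molecular/SES surface), with a
  four-element radius table; per-atom charge models are out of scope.
* pI assumes free termini and independent ionization; post-translational
  modifications and charge coupling are ignored, as in all
  Bjellqvist-style calculators.
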