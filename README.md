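# qtykit

Multi-pass membrane proteins — transporters, channels, receptors — carry 5–11
hydrophobic transmembrane (TM) α-helices and therefore need detergents to stay
in solution once stripped from the lipid bilayer. The **QTY code** is a
deterministic design rule that renders such proteins water-soluble while
preserving the fold: inside each TM helix, every

| native | replacement | rationale |
|--------|-------------|-----------|
| Leu (L) | Gln (Q) | similar side-chain shape, polar amide |
| Ile (I) | Thr (T) | β-branched, polar hydroxyl |
| Val (V) | Thr (T) | β-branched, polar hydroxyl |
| Phe (F) | Tyr (Y) | aromatic, polar hydroxyl |

is substituted, and nothing outside the TM spans is touched.

`qtykit` implements this transform and the full analysis a design study needs
around it:

* **Sequence level** — variation percentages (overall and TM-restricted),
  isoelectric point pI from the Bjellqvist pKa model (bisection on the net
  charge `Z(pH) = Σ_basic 1/(1+10^(pH−pKa)) − Σ_acidic 1/(1+10^(pKa−pH))`),
  average molecular weight, Kyte–Doolittle GRAVY, and text alignments of
  native vs variant.
* **Structure level** — PDB/mmCIF ingestion, residue correspondence with
  loop trimming, Kabsch (SVD) superposition with PyMOL-style iterative
  outlier rejection (`RMSD = √(Σ‖p − (Rq+t)‖²/n)`), and TM-domain-only
  comparisons.
* **Surface level** — Shrake–Rupley solvent-accessible surface area with a
  deterministic golden-spiral point sphere, summarised as the *hydrophobic
  surface fraction* (share of SASA on A/V/L/I/P/F/M/W residues), which
  quantifies how QTY substitution shrinks the hydrophobic TM patches.
* **Synthetic data** — a generator of membrane-protein-like sequences,
  TM topologies and consistent α-helical bundle coordinates (with noise and
  rigid displacement), so every stage is testable without downloading
  UniProt/PDB/AlphaFold-DB inputs.

All user-facing functions take and return tibbles and compose with the pipe;
fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(qtykit)

spec   <- bundle_spec(n_helices = 6, helix_len = 22, loop_len = 6, seed = 42)
prot   <- generate_membrane_protein(spec, id = "demo")
record <- qty_transform(prot$sequence, prot$topology)
record[, c("n_substitutions", "total_variation_pct", "tm_variation_pct",
           "pi_native", "pi_variant", "mw_native", "mw_variant")]
#>   n_substitutions total_variation_pct tm_variation_pct pi_native pi_variant
#> 1              79                45.4            59.85      9.32       8.95
#>   mw_native mw_variant
#> 1  19501.72   19991.41
```

79 of the 132 helix residues are L/I/V/F and get substituted — 59.85 % of the
TM positions change, yet the pI moves by only 0.37 units and the mass by
~490 Da (2.5 %): the chemistry of the surface changes, not the gross
physicochemistry. Structure comparison of the native bundle against a
noise-perturbed, rigidly displaced copy relabelled by the QTY rule:

```r
native  <- generate_bundle_structure(spec)
variant <- perturb_structure(native, sigma = 0.5,
                             angles = c(0.4, -0.7, 1.1),
                             translation = c(8, -4, 6), seed = 7) |>
  qty_relabel(prot$topology)
superpose_structures(native, variant)
#> Rigid superposition (Kabsch + outlier rejection)
#>   pairs: 132 input, 129 used
#>   RMSD:  0.868 A (all pairs), 0.835 A (refined)
#>   cycles run: 2
```

The fit recovers the displacement and reports the residual noise
(σ√3 ≈ 0.87 Å). On the surface side:

```r
hydrophobic_surface_fraction(shrake_rupley_sasa(native))
#> [1] 0.7876
hydrophobic_surface_fraction(shrake_rupley_sasa(qty_relabel(native, prot$topology)))
#> [1] 0.1941
```

— the hydrophobic share of the accessible surface drops from 79 % to 19 %
under the QTY relabelling, the numeric counterpart of the hydrophobic
patches vanishing from a surface rendering. `render_alignment(record,
prot$topology)` prints the classic native/marker/variant text blocks with the
helices flagged above the sequence.

Batch studies are driven by a manifest (`read_manifest()` + `run_report()`),
which yields one row per protein with all sequence metrics and whole-chain
plus TM-only RMSDs, isolating per-entry failures. A thin CLI covering
`transform`, `report`, `superpose`, `sasa` and `simulate` lives at
`inst/scripts/qty-cli.R`.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "qtykit", load_package = "installed")'
```

The suite checks each stage against an independent oracle: a dense-grid scan
of the net-charge curve for pI, an atomic-composition mass sum for MW, direct
numerical optimisation (and `bio3d::fit.xyz`) for the Kabsch fit, analytic
sphere/two-sphere areas and a latitude–longitude quadrature for SASA, and
closed-form helix geometry for the generator.

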