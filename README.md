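# ligmodes

Classification of protein–ligand binding modes from structures and
dose-response data, built around the allosteric antagonist site at the
GluN1/GluN2B N-terminal-domain (NTD) dimer interface of the NMDA receptor.

GluN2B-selective NMDA-receptor antagonists are chemically diverse —
ifenprodil-like phenylethanolamines on one hand, compounds like EVT-101 on
the other — yet all bind the same interface cavity. They do so in (at least)
two geometrically distinct modes that share a hydrophobic anchor subcavity
but diverge elsewhere. `ligmodes` provides the computational pipeline that
classifies a bound or docked pose into such mode families, for structural
biologists and computational chemists working on this receptor or on any
pocket with a comparable multi-mode pharmacology.

## What it computes

* **Interaction fingerprints** — for ligand $L$ and residue-panel entry $p$:
  $d(L,p) = \min_{i \in L, j \in p} \lVert x_i - x_j \rVert$ over heavy
  atoms, giving a ligands × panel matrix in Å. The default panel
  (`interface_panel()`) is the 34 interface residues (13 GluN1 = chain A,
  21 GluN2B = chain B) plus 3 pocket waters.
* **Binding-mode clustering** — euclidean distances between fingerprint
  rows, agglomerative hierarchical clustering (complete linkage by default),
  cut at a relative height (default 0.5) into primary mode classes; ordered
  heatmap data, dendrogram and assignment exports.
* **Cavity volumetrics** — cubic-lattice pocket volume bounded by
  inclusion/exclusion spheres with clash removal at vdW radius + padding
  (defaults: spacing 1.0 Å, padding 1.09 Å); ligand-occupied volume within a
  1.6 Å neighbour-search radius; the *common pocket* of two ligands as the
  arithmetic mean of their cross-occupied volumes.
* **Superposition** — Kabsch least-squares rotation (reflections excluded)
  on Cα atoms paired by chain and residue number, with RMSD and auditable
  pair counts.
* **Hill dose-response fits** — $I_{rel} = 1 - a/(1 + (IC_{50}/[C])^{n_H})$,
  with optional fixing of the maximal inhibition $a$ to 1, bounded
  multi-start Levenberg–Marquardt, and mutant/wild-type IC50 fold changes.
  The published wild-type and mutant parameter estimates for this receptor
  ship as `reference_ic50_panel()`.
* **Synthetic fixtures** — seeded generators for a panel-complete two-chain
  receptor, two-archetype pose sets, wall-atom pocket fixtures with
  closed-form volumes, and Hill-model datasets.

## Worked example

```r
library(ligmodes)

receptor  <- make_two_chain_receptor(seed = 1)
complexes <- make_pose_set(receptor, n_per_class = 5, jitter_sd = 0.3, seed = 1)
fm <- fingerprint_matrix(complexes, "LIG", interface_panel())
fm
#> <fingerprint_matrix> 10 ligands x 37 panel entries
#>   no cap: missing entries kept as NA (drop columns before clustering)

round(fm$values[c(1, 6), c("A:75", "B:114", "B:176", "B:236", "A:109", "B:135")], 2)
#>         A:75 B:114 B:176 B:236 A:109 B:135
#> ifen_01 3.69  4.72  3.93  4.18 10.19  3.90
#> evt_01  5.07  4.70  3.56 10.43  4.35  3.53
```

Both archetypes sit close to the anchor residues (A:75, B:114), but only the
ifenprodil-like pose reaches the lower-lobe residue B:236 (4.18 Å vs
10.43 Å), and only the EVT-101-like pose contacts the groove residue A:109
(4.35 Å vs 10.19 Å) — the geometric signature that separates the two modes.
Clustering recovers the designed classes:

```r
cut_dendrogram(agglomerate(row_distances(fm)), "relative_height", 0.5)
#> <cluster_assignment> k = 2 (relative height 0.5 (cut at 12.13))
#> ifen_01 ifen_02 ifen_03 ifen_04 ifen_05  evt_01  evt_02  evt_03  evt_04  evt_05
#>       1       1       1       1       1       2       2       2       2       2
```

Dose-response analysis, here recovering the ~56-fold IC50 shift of the
GluN2B-F114S mutant against EVT-101 from simulated triplicate data at 3%
noise:

```r
wt  <- fit_hill(make_dose_response(12,  n_h = 1, a = 0.90, seed = 1))
mut <- fit_hill(make_dose_response(676, n_h = 1, a = 0.91, seed = 2))
wt
#> <hill_fit> IC50 = 12.07 nM, n_H = 1.06, a = 0.894 (converged, SSR 0.000358, n = 8)
ic50_ratio(mut, wt)
#> [1] 56.87019
format_fold_change(ic50_ratio(mut, wt))
#> [1] "57"
```

The fitted IC50s (12.07 and 686.5 nM) recover the generating values (12 and
676 nM) within sampling error, and their ratio the published fold change.

## Package layout

| Area | Functions |
| --- | --- |
| Structure I/O & selection | `parse_structure`, `read_structure`, `write_structure`, `read_sdf_pose`, `select_atoms`, `extract_ligand`, `residue_panel`, `interface_panel` |
| Fingerprints | `min_distance`, `fingerprint_matrix`, `contact_map`, `drop_missing_columns` |
| Clustering | `row_distances`, `agglomerate`, `cut_dendrogram`, `ordered_matrix` |
| Volumetrics | `sphere_spec`, `grid_spec`, `build_grid`, `pocket_volume`, `ligand_occupied_volume`, `common_pocket`, `connected_component` |
| Superposition | `pair_ca`, `kabsch`, `superpose_ca`, `transform_structure` |
| Dose-response | `hill_model`, `fit_hill`, `ic50_ratio`, `reference_ic50_panel`, `simulate_ratio_recovery` |
| Synthetic data | `make_two_chain_receptor`, `make_pose`, `make_pose_set`, `make_pocket_fixture`, `make_dose_response` |
| Runners / CLI | `run_fingerprint`, `run_cluster`, `run_volume`, `run_hillfit`, `run_simulate`; wrapper in `inst/cli/ligmodes.R` |

The methods vignette (`vignettes/binding-mode-classification.Rmd`) documents
the models, numerical conventions, design decisions and limitations.
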