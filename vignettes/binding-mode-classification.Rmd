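---
title: "Classifying antagonist binding modes at the GluN1/GluN2B NTD interface"
author: "ligmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying antagonist binding modes at the GluN1/GluN2B NTD interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligmodes)
```

## The scientific problem

GluN2B-selective antagonists of the NMDA receptor — ifenprodil and its
phenylethanolamine relatives, but also chemically unrelated compounds such as
EVT-101 — all act at the same allosteric site: the interface between the
GluN1 and GluN2B N-terminal domains (NTDs). Crystal structures show that this
interface cavity is large enough to host at least two geometrically distinct
binding poses: the classic "phenylethanolamine" pose that reaches down toward
the GluN2B lower lobe, and a second pose that shares the hydrophobic anchor
subcavity at the upper-lobe interface but branches into a solvent-exposed
groove along the GluN2B β4-β5 loop. Whether an arbitrary antagonist adopts
one or the other mode matters for structure-based design, and it can be read
out computationally from a bound or docked pose.

`ligmodes` implements the quantitative pipeline for that readout:

1. **Interaction fingerprints** (`fingerprint_matrix()`): each pose is
   summarised by its vector of minimum heavy-atom distances (Å) to a fixed
   panel of 34 interface residues and 3 pocket waters (`interface_panel()`;
   chain A = GluN1, chain B = GluN2B, W = water).
2. **Binding-mode clustering** (`agglomerate()`, `cut_dendrogram()`):
   euclidean distances between fingerprint rows, agglomerative hierarchical
   clustering, and a relative-height cut that exposes the primary pose
   families.
3. **Cavity volumetrics** (`build_grid()`, `pocket_volume()`,
   `ligand_occupied_volume()`, `common_pocket()`): grid-based volume of the
   interface cavity and of the sub-volumes each ligand occupies, including
   the "common pocket" shared by two binding modes.
4. **Superposition** (`superpose_ca()`): Kabsch Cα RMSD between isomorphous
   structures, used as a sanity check that the protein itself is unchanged
   between ligand complexes.
5. **Dose-response analysis** (`fit_hill()`, `ic50_ratio()`): Hill fits of
   mutant-receptor electrophysiology, whose mutant/wild-type IC50 fold
   changes are the functional validation of a binding mode.

## Models and their assumptions

### Minimum-distance fingerprints

For ligand $L$ and panel entry $p$ the fingerprint value is

$$ d(L, p) \;=\; \min_{i \in L,\, j \in p} \lVert x_i - x_j \rVert, $$

over *heavy* atoms only. Hydrogens are excluded by default because crystal
structures at 2.8–3.0 Å resolution carry none while docked poses may; the
exclusion makes the two sources comparable (`include_hydrogens = TRUE`
overrides). Whole residues — backbone plus side chain — enter the minimum:
backbone carbonyls are genuine ligand contacts in this pocket (the
GluN2B-Q110 and A135 main-chain interactions), so restricting to side chains
would misrepresent them. No distance cap is applied during computation; a cap
only matters as a display convention for heatmaps and as a sentinel for panel
entries that fail to resolve (see below).

Fingerprints are invariant under rigid motion of the complex and under panel
reordering (columns permute identically); these invariants are enforced by
property tests.

**Missing entries.** A water token may be absent from a docked pose file.
With a cap set, missing entries are encoded as the cap value (sentinel);
without one they stay `NA` and `drop_missing_columns()` must be applied
before clustering. `row_distances()` refuses `NA`s rather than silently
imputing; the policy in effect is recorded on the object and in the run
report.

### Clustering

Rows are compared with plain (unscaled) euclidean distance — the natural
choice since all columns are distances in the same unit. The linkage is
**complete** by default: the clustered-heatmap tooling this analysis mirrors
uses complete linkage as its default, and the published account states the
metric but not the linkage. Single and average linkage are available and the
choice is recorded in the run report; for well-separated pose families the
top-level bipartition is linkage-independent (tested with inter/intra
separation ratio ≥ 3). Merging is performed by `stats::hclust`, whose merge
procedure is deterministic, so repeated runs are bitwise reproducible.

The "primary clusters" cut removes merges above a fraction (default 0.5) of
the maximum merge height. A clean two-mode structure appears as exactly two
clusters whenever the final merge is more than twice as high as every
within-mode merge; `fixed_k` is available when the number of classes is known
a priori. Column (residue) clustering is computed only to order heatmap
columns and never feeds classification.

### Grid volumetrics

The cavity is sampled on a cubic lattice (spacing 1.0 Å by default) covering
the bounding box of one or more *inclusion spheres*; *exclusion spheres*
carve away neighbouring cavities and bulk solvent. A lattice point survives
if it lies in at least one inclusion sphere, in no exclusion sphere, and at
distance greater than $r_{vdW} + \mathrm{padding}$ from every heavy protein
atom. The pocket volume is the surviving count times $\mathrm{spacing}^3$.

Numerical conventions, all recorded in the outputs:

* **Padding semantics** (default 1.09 Å): added to each atom's van der Waals
  radius in the clash test. A bare number is dimensionally ambiguous; this is
  the documented behaviour of the grid-volumetrics tools this module
  re-implements, and it is flagged as an assumption.
* **vdW radii**: a pinned Bondi-style element table shipped in the package
  (`vdw_radius()`), with a warned carbon-like fallback (1.70 Å) for exotic
  elements. Pinning the table makes volume numbers reproducible across
  environments.
* **Lattice phase**: anchored at the inclusion bounding-box minimum corner,
  not at any atom. Absolute point counts therefore depend on the sphere
  configuration only; joint rigid motion of spheres + structure changes
  volumes only by boundary-shell jitter (tested at ≤ 5%).
* **Contiguity**: no connected-component filtering by default, because a
  well-chosen exclusion-sphere set already isolates the pocket; an optional
  6-connected flood fill (`connected_component()`) is provided.
* Boundary conventions are closed (distance ≤ radius counts as inside a
  sphere), so an exclusion sphere congruent with an inclusion sphere removes
  every point.

Ligand occupancy counts pocket points within a neighbour-search radius
(default 1.6 Å) of any ligand heavy atom; the *common pocket* of two modes is
the arithmetic mean of the two cross-occupied volumes.

Correctness is established against closed forms: a hollow wall-atom shell of
radius $R$ has accessible radius $R - r_{vdW} - \mathrm{padding}$, hence
volume $\tfrac43 \pi (R - r_{vdW} - p)^3$ (`make_pocket_fixture()`), and the
grid estimate converges to it as spacing shrinks — within 2% at 0.5 Å for the
default fixture, monotonically through spacings 2 → 1 → 0.5 Å. The residual
positive bias at finite wall-atom spacing is the scalloping of the clash
surface between wall atoms; it shrinks with finer walls, and the fixture
generator refuses wall spacings coarse enough to leak.

### Superposition

`kabsch()` computes the least-squares proper rotation (reflections excluded
by the determinant correction in the SVD construction) plus translation, and
reports the post-fit RMSD. Cα pairing (`pair_ca()`) is by chain map and
residue number, *not* sequence alignment: the intended comparisons are
isomorphous crystals of the same construct, where residue numbering is
shared. Residues lacking a Cα partner are skipped and per-chain pair counts
are reported so the selection entering any RMSD figure is auditable.
Degenerate (collinear) point sets are rejected rather than silently fit. The
implementation is verified against a fine rotation-angle grid search and an
independent library route.

### Hill dose-response fits

The inhibition model is

$$ I_{rel} = 1 - \frac{a}{1 + (IC_{50}/[C])^{n_H}}, $$

with $I_{rel}$ the current normalised to the no-compound current, $a \in
(0, 1]$ the maximal inhibition and $n_H$ the Hill coefficient. Fitting is
bounded Levenberg–Marquardt least squares on $I_{rel}$:

* $IC_{50}$ is fitted on the log scale (it is a scale parameter spanning
  9–11,400 nM across the mutant panel);
* bounds $n_H \in [0.2, 5]$, $a \in (0, 1]$;
* multi-start initialisation over the concentration quartiles for $IC_{50}$
  and $n_H \in \{0.7, 1.0, 1.4\}$ (bracketing the slopes observed for these
  antagonists); the lowest final residual wins, exact ties going to the lower
  $IC_{50}$;
* `fix_a = TRUE` pins $a = 1$ exactly, mirroring the published fits for
  mutants whose inhibition saturates completely;
* the `converged` flag is honest — a non-converged fit is returned as such,
  never replaced by a best guess, and `ic50_ratio()` refuses non-converged
  inputs.

Replicate weighting (1/sd²) is available but **uniform weights are the
default**: the published analysis does not state a weighting scheme, and
uniform weighting is the conservative reading. Censored IC50 entries
(">10000 nM") are carried as bounds, flagged, and excluded from ratio
arithmetic. Ratios are stored full-precision and printed at two significant
figures (`format_fold_change()`).

## What the synthetic generators emulate

`make_two_chain_receptor()` builds a minimal two-chain cleft whose residue
numbering covers the full interface panel: tri-atom (N, CA, C) glycine stubs
arranged on rings around three subcavity centres — a shared hydrophobic
anchor at the origin, a "lower-lobe" branch at (8, 0, 0) and a "groove"
branch at (0, 8, 0) — with chain A forming the wall at z > 0 and chain B at
z < 0, plus the three pocket waters. Tri-atom stubs are deliberate: they are
enough for selection and whole-residue distance semantics without
pretending to model side chains.

`make_pose()` draws the two archetypes: both place half their atoms at the
anchor, and the branch half in the archetype's subcavity; the 8 Å branch
separation makes fingerprint rows separate by construction (inter/intra
distance ratio ≈ 10 at the default 0.3 Å jitter, comfortably above the ≥ 3
the clustering properties require). The default study condition for
recovery experiments is 10 + 10 poses at 0.3 Å jitter.

`make_dose_response()` uses the generating condition applied throughout the
recovery studies: 8 log-spaced concentrations over $[IC_{50}/100,\,
100 \cdot IC_{50}]$, triplicate, 3% multiplicative Gaussian noise truncated
at 0. The design is centred on the true IC50 because the published work
shows full inhibition curves without stating its concentration grids; 3%
matches the order of magnitude of the tabulated standard deviations. The
generating Hill coefficient defaults to $n_H = 1.0$, the midpoint of the
reported 0.6–1.4 range, since per-receptor values are not tabulated.

**What the generators do not emulate** — and hence what passing tests do not
show about real data: physically realistic protein geometry, side-chain
packing, induced fit, docking-pose errors, correlated (non-multiplicative)
electrophysiology noise, rundown, and series-resistance artefacts. The
synthetic pipeline demonstrates that the *computations* are correct and that
the classification is recoverable under its designed separation; it cannot
certify docking quality or recording quality.

## Study conditions recomputed by `scripts/acceptance.R`

The acceptance script regenerates, from scratch at a user-supplied seed: the
six key mutant/wild-type fold changes (10 simulation seeds each, mean
reported), the two-class recovery rate over 100 pose-set seeds, the
sphere-fixture volume error at 0.5 Å spacing, the common-pocket mean of the
(100, 50) example, and the Monte-Carlo median |IC50 error| across the
non-censored reference parameter sets (3 seeds per set). Problem sizes were
chosen so the whole script completes in well under a minute on a single
core while keeping Monte-Carlo error far below the quantities' tolerances.

The checks that require the deposited crystal structures (nearest-distance
values of 3.53 Å vs 5.33 Å to GluN2B-F176, and the 0.36 Å Cα RMSD between
the ifenprodil complex and the prior apo-form entry) run only when those
entries are available locally or downloadable; they are not part of the
synthetic recomputation.

## Worked example

```{r example}
receptor <- make_two_chain_receptor(seed = 1)
complexes <- make_pose_set(receptor, n_per_class = 5, jitter_sd = 0.3, seed = 1)
fm <- fingerprint_matrix(complexes, "LIG", interface_panel())
fm

dend <- agglomerate(row_distances(fm))
cut_dendrogram(dend, "relative_height", 0.5)
```

```{r hill}
wt <- fit_hill(make_dose_response(12, n_h = 1, a = 0.9, seed = 1))
mut <- fit_hill(make_dose_response(676, n_h = 1, a = 0.91, seed = 2))
ic50_ratio(mut, wt)
format_fold_change(ic50_ratio(mut, wt))
```

## Known limitations

* Pose quality is upstream: the package consumes one pose per ligand and
  neither docks nor rescores; pose selection ("best pose by energy and
  inspection") is the caller's responsibility.
* Water numbering is treated as file-local; panel water tokens are not
  guaranteed to correspond across differently processed structures.
* The exact exclusion-sphere set used for any published cavity volume is
  configuration, not code; the module accepts arbitrary sphere lists and
  ships only fixtures with closed-form volumes as ground truth.
* Cα pairing by residue number fails for constructs with different
  numbering; sequence-alignment pairing is out of scope by design.
* Insertion codes are rejected rather than normalised; renumber such inputs
  upstream.
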