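---
title: "Multiscale descriptors and the evaluation protocol of fesred"
author: "fesred authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale descriptors and the evaluation protocol of fesred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fesred)
```

## The problem

The midpoint reduction potential (RP, in mV vs SHE) of an iron–sulfur
protein is tuned over nearly a volt by the protein matrix around the metal
site: the identity of the ligating residues, hydrogen bonding to the
sulfides, the polarity and charge of the second and outer coordination
spheres, and global electrostatics. `fesred` predicts RP from a static 3D
structure for two site chemistries — the mononuclear rubredoxin-type Fe(Cys)4
site and the binuclear [2Fe–2S] cluster (ferredoxin-, Rieske- and
mitoNEET-type coordination) — by summarizing the residue environment of the
cofactor at three spatial scales and regressing RP on those descriptors with
gradient-boosted trees.

## The descriptor model

Every spatial region is summarized by the same **66-descriptor block**
computed from residue identities alone:

* 11 class counts (total residues; neutral-polar, hydrophobic, aromatic,
  basic, acidic, charged, all-polar; Cys; His; Gly/Pro). The grouping
  convention is fixed: cysteine counts as neutral polar; histidine, lysine
  and arginine count as basic/positively charged (His is also aromatic; the
  flags are not a partition).
* 20 per-amino-acid counts.
* 18 property sums and 17 property means over the table returned by
  `aa_properties()`: hydropathy (Kyte–Doolittle), residue volume
  (Zamyatnin), steric hindrance (Zimmerman bulkiness), backbone flexibility
  (Bhaskaran–Ponnuswamy), Grantham polarity, isoelectric point, residue
  mass, net side-chain charge at neutral pH, hydrogen-bond donor/acceptor
  group counts, side-chain N/O/S atom counts, maximal solvent-accessible
  area, and the three Chou–Fasman propensities; plus the
  *steric + flexibility composite* `steric.flex` (the sum of the z-scores of
  bulkiness and flexibility across the 20 residues), summed only. The table
  is a frozen, versioned constant; a drop-in replacement with the same
  columns can be supplied for replication against other parameterizations.

The regions of the default (strategy A) schema, at radii `r1` (medium range,
8–16 Å) and `r2` (short range, 3–5 Å, `r2 < r1`):

| block | region | scale |
|---|---|---|
| `Protein` | all standard residues | long |
| `Bar` | residues within `r1` of the cofactor barycenter | medium |
| `Shell1` | the first coordination sphere (residues with a side-chain atom within 3.0 Å of an Fe) | short |
| `CofAtom.Fe`, `CofAtom.S` | residues within `r2` of any Fe / any inorganic S | short |
| `CofAtom.Fe1/Fe2/S1/S2` | residues within `r2` of each individual cofactor atom | short |
| `CofAtom.All` | residues within `r2` of any cofactor atom | short |

plus the 28 nearest-residue descriptors (`NearestFe.X`, `NearestS.X`: 14
properties of the residue closest to each cofactor element), the 32
sequence-neighborhood descriptors (`AroundFe.X`, `AroundS.X`: 16 aggregates
over the nearest residue and its two sequence neighbors), the cofactor
inventory (counts of other hetero cofactors over a fixed 14-code vocabulary
× three scopes: whole structure, `r1` sphere, `r2` sphere, excluding the
focal site, plus the focal site's own Fe and S multiplicities) and pH as a
numeric condition feature:

$$10 \times 66 + 28 + 32 + (14 \times 3 + 2) + 1 = 765$$

The 765 total and the 66/28/32 block sizes are fixed schema invariants. The
printed block sizes alone do not determine a unique region layout; the
breakdown above — per-element *and* per-atom short-range regions plus the
explicit first coordination sphere — is this package's documented choice,
selected so that the short-range descriptors resolve "the environment of
each atom of the cofactor" while the per-element unions keep a
multiplicity-independent summary. On mononuclear sites every block that
refers to an absent atom (all `*S*` blocks, `CofAtom.Fe2`) is zero-filled,
never `NA`.

Strategy B is the deduplicated union of strategy-A features across the full
radii grids: radius-independent blocks once, `Bar` once per `r1` (9×),
cofactor-atom blocks once per `r2` (3×), sphere-scoped inventory entries per
radius — 2357 features, each unique strategy-A feature exactly once.

### Geometric conventions

* A residue belongs to a sphere if **any** of its non-hydrogen atoms lies
  inside, boundary inclusive (configurable to C-alpha or side-chain-centroid
  assignment; the any-atom rule is the tested default). Membership uses a
  10⁻⁹ Å tolerance so residues placed exactly on a boundary are included
  regardless of floating-point round-off.
* The barycenter is the unweighted mean of the cofactor atom coordinates;
  for rubredoxin-type sites it is the Fe position.
* Fe–ligand bonds use a 3.0 Å cutoff from any Fe to any side-chain atom
  (covers Fe–S(Cys) ≈ 2.3 Å and Fe–N(His) ≈ 2.1 Å with margin).
* Nearest-residue searches compare distances at 0.01 Å granularity — coarser
  than the 10⁻³ Å precision of PDB coordinate fields, so a structure written
  to disk and re-read ranks residues identically — with ties broken by chain
  id, then residue number.
* Alternate locations keep the highest-occupancy copy (ties: altloc letter,
  'A' first); only the first MODEL of multi-model files is used; hydrogens,
  waters and non-target hetero groups never enter residue regions.
* Ligating residues are not excluded from the `r2` neighborhoods: they
  satisfy the distance rule and the first sphere is chemically the dominant
  RP determinant, so removing them would discard the strongest signal. The
  `Shell1` block makes the first sphere available to scale ablations as an
  explicit short-range region.

## The evaluation protocol

`fesred()` estimates generalization by **nested cross-validation**: a 5-fold
outer loop scores held-out folds; within each outer training set a 10-fold
inner grid search selects, by minimal MAE, one of 108 hyperparameter
configurations (tree depth 3/4/5 × 100/150/200 rounds × learning rate
0.01/0.1/0.2/0.4 × minimum child weight 1/5/10 — a grid oriented toward
regularization, since features outnumber entries). The whole procedure is
repeated 10 times with reshuffled folds; metrics (MAE, RMSE, R², Spearman
correlation) are reported as mean ± sd over all 50 outer folds × repeats.
Fold assignment is random at the entry level — mutants and pH replicates of
one protein may straddle folds — matching the main protocol; the
protein-level regime lives in `leave_proteins_out()`, which removes every
entry of the held-out proteins, and `leave_mutants_out()`, which scores held-
out mutants and compares the *direction* of the predicted shift against the
wild type (shifts below a 5 mV dead-band count as "essentially unchanged";
the dead-band value is this package's choice). Train/test disjointness is
asserted programmatically on every split, and a fixed seed reproduces folds,
selected hyperparameters and metrics bit-identically (single-threaded
boosting).

The linear baseline uses ordinary least squares when rows comfortably exceed
columns and a cross-validated ridge fit otherwise: with 765–2357 features
and a few hundred entries plain least squares is ill-posed, and the baseline
is a control, not a contribution. Boosting settings outside the grid stay at
library defaults and are recorded in the evaluation object.

`scan_radii()` evaluates all 27 (`r1`, `r2`) cells; it featurizes each
structure once via the strategy-B union and takes column subsets per cell,
which makes the scan's cost one featurization pass plus one nested CV per
cell. `ablate_scales()` retrains on scale-masked column subsets (pH is an
experimental condition, not a structural scale, and stays in every variant);
variant differences are tested pairwise with the two-sided Mann–Whitney U
test on fold-level MAEs (exact p-values for small untied samples, e.g.
p = 0.1 for fully separated triples).

Attributions use exact TreeSHAP on the gradient-boosted model: per-row
additive contributions in mV whose sum plus the base value equals the
prediction. The reporting protocol (`cv_shap_importance()`) fits a model per
outer fold and attributes its own held-out rows, then averages mean absolute
attributions across folds; importance heatmaps across radii normalize per
model (each column by its maximum) and order features by cross-model mean.
Local accuracy is enforced with a scale-aware tolerance,
`max(1e-4, 1e-5 · max|prediction|)` mV, because the booster accumulates tree
leaves in single precision. `spearman_feature_rp()` complements attribution
with per-feature rank correlations against RP (constant features are
flagged undefined rather than zero).

## The synthetic test bed

Real Fe–S structures and curated RP tables cannot ship with the package, so
every protocol is exercised on generated data whose truth is known exactly.

`make_toy_structure()` builds valid, column-exact PDB files: a [2Fe–2S]
rhombus (Fe–Fe 2.7 Å, Fe–S 2.2 Å) or single Fe at the origin, four ligating
residues with their ligating atom at exactly 2.3 Å from an Fe, and shell
residues whose nearest atom (C-alpha) sits exactly at a specified barycenter
distance, with all other atoms strictly farther out — so per-residue
distances are known by construction and neighborhood memberships can be
asserted against an independent brute-force scan. Residue directions are
randomized with clash rejection; any residual atom pair closer than 0.8 Å
aborts generation. Synthetic mutants substitute residue identities at fixed
coordinates (no repacking), which suffices because all descriptors depend
only on identity and geometry.

`make_synthetic_dataset()` draws RP from a known linear model
`RP = b0 + Σ w·x + N(0, σ)` over schema features. Its defaults define the
package's study conditions and were chosen once, as follows:

* **Population shape**: 50 proteins × (1 wild type + 2 mutants) × 2 pH
  conditions = 300 entries, i.e. ~6 entries per parent protein — matching
  the entry-to-protein ratio of curated Fe–S RP compilations (a few hundred
  entries over a few dozen proteins). Protein-level signals are only
  identifiable when enough independent proteins exist; concentrating the
  same 300 entries on fewer proteins confounds protein-constant features
  with protein identity.
* **Support (k = 5)**: pH; the whole-protein aromatic count; the number of
  peripheral FAD and of HEM cofactors (the generator places 0–2 of each at
  15–25 Å); and the Fe-adjacent steric+flexibility composite
  (`AroundFe.sum.steric.flex`). These are five *distinct channels* —
  condition, long-range composition, inventory, short-range — chosen to be
  approximately orthogonal in the synthetic population. That matters for
  the attribution-recovery test: descriptors with near-exact aliases in the
  schema (a property sum and its mean at fixed chain length, say) split
  TreeSHAP credit between the copies, and a test built on such a support
  would measure collinearity, not attribution.
* **Weights** (−30 mV/pH unit, +25 mV/aromatic residue, +60 and −55 mV per
  cofactor copy, −35 mV per composite unit) equalize the per-channel signal
  contribution at roughly 25–50 mV sd each, for a total RP sd of
  ~100–130 mV and a range of about ±300 mV around −60 mV — comparable to
  the span of experimentally characterized Fe–S proteins. Measurement noise
  defaults to σ = 20 mV.

What the generator does **not** emulate: real backbone geometry and
rotamers, structural relaxation upon mutation, correlated measurement error
between techniques, and class-specific first-sphere chemistry beyond the
mono/binuclear distinction. Passing tests therefore certify the machinery —
parsing, geometry, schema assembly, protocol integrity, attribution — and
the recoverability of known signal at realistic noise, not predictive
accuracy on real proteins; the headline accuracies of the original study
can only be reproduced with its curated structures and measurements, which
the pipeline accepts unchanged through `load_dataset()` +
`build_design_matrix()`.

## Problem sizes used by the shipped checks

The package's own acceptance runs use desk-scale protocol sizes, stated here
as the package's choices: nested CV on the 300-entry synthetic set with a
4-configuration subgrid (depth 3/4 × learning rate 0.1/0.2, 100 rounds,
child weight 5), 5 outer × 3 inner folds, 1 repeat; attribution recovery
over 20 generator seeds with 5-fold attribution; geometry oracles over 100
random structures. The full 108-configuration, 5×10×10 protocol is the
default of `fesred()`/`nested_cv()` and is what a study on real data should
run.

## Numerical and degenerate-input choices

* Constant targets flag R² and Spearman as undefined (`NA`) rather than
  failing; degenerate outer folds (fewer than 2 rows) error.
* Grid enumeration is lexicographic over (depth, rounds, learning rate,
  child weight); inner-loop ties resolve to the earliest configuration.
* Mann–Whitney p-values fall back to the normal approximation in the
  presence of ties (identical samples report p ≈ 1, asserted ≥ 0.99).
* The empty region yields the all-zero 66-block; property means over an
  empty region are 0 by the same zero-fill convention.
* pH outside [0, 14], RP outside [−1000, 1000] mV, duplicate entry ids and
  unknown protein classes are itemized loader errors naming the row.

## Known limitations

* Only FES (binuclear) and isolated-Fe hetero groups are recognized as
  focal sites; [3Fe–4S]/[4Fe–4S] clusters appear in the inventory
  vocabulary but are not modeled as sites.
* Descriptors are static; conformational ensembles, protonation states and
  electrostatics solvers are out of scope by design.
* The residue property table is a standard published parameterization, not
  the exact table of any particular prior study; replication against other
  parameter sets should supply a replacement table.
* mmCIF input is not supported; structures must be PDB-format text.
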