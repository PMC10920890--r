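---
title: "Methods: voxelized microenvironments, masked-residue networks, and kinetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelized microenvironments, masked-residue networks, and kinetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voxdesign)
```

## The pipeline

`voxdesign` implements a structure-based protein-engineering stack built on
masked-residue prediction. The idea: remove one residue's atoms from a
protein structure, featurize the surrounding atomic neighbourhood — protein,
ligands, cofactors, ions and nucleic acids alike — and train a 3D
convolutional network to predict which of the 20 amino acids belongs there.
Residues where the network prefers a non-native amino acid are candidate
substitutions; the log-odds between the preferred and native amino acid
ranks them. Around that core the package carries the quantitative analyses
a protein-engineering campaign needs downstream: global fitting of
mass-action enzyme kinetics (with a substrate-inhibition variant) with
profile-chi-square confidence contours, Hill dose-response fits for
biosensor EC50s, and Boltzmann melt fits for DSF Tm values.

The stages map onto the package API:

1. **Structure preparation** — `read_structure()`, `assign_partial_charges()`,
   `compute_sasa()`, `filter_by_resolution()`.
2. **Microenvironment sampling** — `find_interface_residues()`,
   `sample_residues()`, `build_frame()`, `extract_microenvironment()`,
   `split_dataset()`.
3. **Voxelization** — `voxelize()`, `batch_voxelize()`.
4. **Model** — `build_model()`, `train_model()`, `evaluate_model()`.
5. **Scoring** — `ensemble_predict_grids()`, `log_odds()`,
   `zero_shot_benchmark()`, `rank_designs()`.
6. **Validation fits** — `fit_kinetics()` / `confidence_contour()`,
   `fit_hill()`, `fit_boltzmann_melt()`.

## Structure preparation

Parsing buys `bio3d` for both PDB and mmCIF. Alternate locations keep the
highest-occupancy conformer, ties broken by file order. Entities are
classified from residue names: standard amino acids are protein, standard
nucleotides nucleic, `HOH`/`WAT` water, single-atom metal/halide residues
ions, and every remaining HETATM group a ligand. Hydrogens are accepted if
present but never added; protonation is out of scope.

**SASA.** Solvent-accessible surface area uses Shrake–Rupley point sampling
with a deterministic Fibonacci lattice (default 960 points, probe 1.4 Å).
Every atom of every entity class occludes every other, so protein:ligand
burial is reflected in the protein atoms' values — the property the voxel
SASA channel is meant to carry across interfaces. The lattice directions are
expressed in a molecule-fixed frame derived from the atom displacement
vectors (farthest atom from the centroid, then the largest orthogonal
component), so a rigid motion of the coordinates rotates the sampling
identically and per-atom SASA is exactly rigid-motion invariant — with a
world-fixed lattice it would drift by a fraction of a percent under
rotation. Determinism matters more here than quadrature elegance: the same
structure always yields the same tensor. The estimator's accuracy (~1% at
960 points against the closed-form two-sphere solution) is far below any
downstream sensitivity.

**Partial charges.** The shipped template is a simplified CHARMM-style
additive table covering the 20 amino acids, water and common ions,
constructed so each neutral residue sums to 0 e and charged groups to their
formal charge. It is a documented stand-in, not a reproduction of any
polarizable charge scheme; workflows with a dedicated charge program feed
its per-atom output back in through `charge_source = "external_file"`.
Atoms without a template entry (most ligands, under the lookup source) get
0.0 e with one summary warning — their element and SASA channels still carry
signal.

## Microenvironments

A residue's microenvironment is the set of atoms inside a 20 Å axis-aligned
cube centered on its C-alpha, expressed in a backbone-oriented frame, with
the residue's own atoms removed. The frame puts +z along the direction from
the C-alpha to a virtual C-beta built from N, CA, C by ideal tetrahedral
geometry (bond 1.522 Å, both flanking angles 110.4°); +x is the component
of N−CA orthogonal to z, +y completes a right-handed triad. Using the
virtual rather than the observed C-beta keeps glycine well-defined and makes
the frame a pure function of the backbone. Cube membership is inclusive
(|coordinate| ≤ 10 Å); waters are excluded from cube content, every other
entity is kept.

**Interface flagging and sampling.** A residue is an interface residue when
any of its atoms is within 5.0 Å (inclusive) of any ligand, nucleic-acid or
ion atom. Waters do not count: crystallographic waters are ubiquitous and
would flag nearly every surface residue. Both toggles are config-exposed.
Per chain, sampling takes every interface residue first and backfills by
seeded uniform draws until `min(200, ceiling(L/2))` residues are reached.
Both clauses of the "200 or half the chain" rule read as caps, and `min` is
the only interpretation under which each can bind; the half-chain rounding
(`ceiling`) and the non-truncation of interface overflow are explicit
choices, both config-exposed, since neither behavior is dictated by the
rule itself. Train/test splitting is 90:10, drawn independently inside the
interface and non-interface strata with round-to-nearest counts, so
interface enrichment is preserved across the split.

## Voxelization

The cube becomes a 20×20×20×9 tensor at 1 Å resolution. Channels 1–7 are
element channels (C, H, O, N, S, P, and a grouped halogen channel F/Cl/Br/I);
channels 8–9 carry partial charge and SASA. Each atom contributes a Gaussian
`exp(−‖v − x‖² / 2σ²)` at surrounding voxel centers with σ = 0.5 × its van
der Waals radius, truncated spherically at 3σ; the charge and SASA channels
add the same field scaled by the atom's charge and SASA. Defaults
concentrate a carbon's density within its van der Waals sphere; amplitude is
1 at the atom center (no mass normalization) with `normalize = TRUE`
available. Elements with no element channel (metals, Se, B, …) contribute to
the physical channels only, or are dropped entirely with
`drop_unchanneled = TRUE`. Voxel centers sit at cell midpoints, so the
tensor is symmetric under the frame conventions above; the test suite pins
the implementation to a brute-force evaluation of the same formula at all
8000 centers (max deviation < 1e-9) and to rigid-motion invariance of the
frame+voxelize composition (< 1e-6).

No rotation augmentation is used — the backbone frame fixes orientation by
construction, which is the point of frame-based featurization.

## The 3D residual network

No tensor/autodiff library ships in this package's dependency set, so the
network is implemented directly: 3×3×3 convolutions computed as 27
offset-indexed BLAS matrix products, ReLU, identity residual blocks, global
average pooling and a dense softmax head. The layout is a stride-2 stem
(9 → `base_width` channels, 20³ → 10³), a stride-2 downsample
(`base_width` → 2×`base_width`, 10³ → 5³), with the residual blocks split
across the two spatial stages. Backpropagation is exact (the test suite
checks analytic gradients against central differences at 1e-4 relative
tolerance) and the Adam optimizer, cross-entropy loss and L2 weight decay of
0.001 on convolution weights are implemented alongside.

Training follows a scheduled learning rate
`lr = 0.001 · exp(−c · epoch) · 0.25^drops` with decay constant c = 0.5 (0.3
as the common alternative), where a drop is taken whenever training accuracy
fails to improve by 0.1 percentage points over a window of 30k training
instances (50k/60k selectable). "Lower the learning rate by 0.25" is read
multiplicatively — subtracting 0.25 from a rate ≤ 0.001 is impossible.
Batches default to 200; each epoch is checkpointed. Because the channels
have wildly different scales (a SASA of 100 Å² versus a unit-amplitude
element Gaussian), per-channel standardization constants are fitted on the
training grids and stored with the model, so inference applies the identical
transform; without this the optimizer conditions poorly.

Class order is fixed alphabetical (`ALA` … `VAL`) in every artifact.
Evaluation reports wild-type accuracy overall and inside ligand-interface,
nucleic-interface and non-interface strata, with `NA` (never 0) for empty
strata and argmax ties broken toward the lowest class index.

## Scoring and benchmarking

Ensembles average member probability vectors (arithmetic mean by default,
logit-mean optional). The mutation score is the natural-log odds
`ln p(mut) − ln p(wt)`; the log base is a scale factor, so correlation-based
benchmarks are unaffected by the choice. `zero_shot_benchmark()` runs the
full featurize→predict→score path per mutation, skips rows whose stated
wild type disagrees with the structure, writes its own Pearson and Spearman
formulas (the `stats::cor` implementations serve as the independent
cross-check in the tests), and declines to report a correlation under three
scorable rows. `rank_designs()` emits the best non-wild-type substitution
per residue with its log-odds, nearest-ligand distance and interface kind —
the raw material a human curator filters for salt bridges, helix caps and
active-site proximity; those heuristics are deliberately not automated.

## Enzyme kinetics

The minimal scheme is E+S→ES, ES→EP, EP→E+P, plus a first-order background
substrate oxidation S→P2 fixed at 0.00547 min⁻¹. Reverse rates of the three
enzymatic steps are locked at 0, product release at 10000 min⁻¹ so it never
limits turnover, leaving `k+1` (= kcat/Km) and `k+2` (= kcat) floating; the
observable is EP + P. The substrate-inhibition variant adds E+S⇌SE,
SE+S⇌SES, ES+S⇌SES with on-rates locked at 100 µM⁻¹min⁻¹, the off-rates
floating as one linked parameter, and `k+5` linked to `k+1`. Setting the
inhibition on-rate to zero reproduces the minimal scheme's trajectories
exactly, a regression test of the scheme plumbing.

Simulation integrates mass-action ODEs with `deSolve::lsoda` at rtol 1e-8 /
atol 1e-12 µM and an analytic Jacobian assembled from the stoichiometry —
without the Jacobian the 10⁴ min⁻¹ release rate makes the corrector
iteration fail at these tolerances. Fitting is global Levenberg–Marquardt
(`minpack.lm`) over all substrate levels and replicates simultaneously, on
log-scaled rates with log-spaced multi-starts. The finite-difference step is
widened (`epsfcn = 1e-6`) so numerical derivatives ride above the
integrator's noise floor. Weights are unit by default; per-point standard
deviations are accepted, and the simulation studies pass the generator's
known 2% multiplicative noise model as σᵢ = 0.02·yᵢ — with unit weights on
heteroscedastic data the homoscedastic χ² threshold undercovers, which is a
property of the threshold, not of the optimizer.

**Confidence contours.** For one rate constant, the profile χ² is computed
by fixing it on a scan grid and refitting the remaining floats. The 95%
interval is the region where `χ²_min/χ²(θ)` stays above
`1 / (1 + p/(n−p) · F₀.₀₅(p, n−p))` with p the number of floating
parameters and n the data points — the standard FitSpace-style form;
the threshold is always computed from the data at hand, never hard-coded.
Two numerical details matter: crossings are interpolated on the
√Δχ² scale, which is locally linear in θ for a near-quadratic profile
(linear interpolation on χ² itself biases intervals inward on coarse
grids), and the default scan range comes from a pilot curvature probe at
±5% so the grid actually resolves the crossing. Sides the scan cannot
bracket are reported open-ended rather than extrapolated — with weak
substrate inhibition this is the expected outcome for the inhibition
constant. On a one-floating-parameter linear fixture this machinery
reproduces the closed-form t-interval, which the test suite checks within
5%.

## Dose-response and melt fits

The Hill equation `y = d + (a − d)xᵇ/(cᵇ + xᵇ)` is fitted by
Levenberg–Marquardt with data-driven starts (d = min y, a = max y, b = 1,
c at the geometric middle of the positive doses); x = 0 is handled by the
equation directly (y = d), so no log-transform is needed. Constant signals
are flagged degenerate with no EC50; dose ranges that do not straddle the
fitted EC50 are flagged unreliable. The melt fit uses the Boltzmann sigmoid
`F = F_min + (F_max − F_min)/(1 + exp((Tm − T)/slope))` on the raw signal —
the parameterization is our choice where only the equation family is named;
fitting the raw rather than derivative curve keeps the noise model simple
for monophasic melts. A crude smoothed-derivative scan detects a second
transition; biphasic curves are flagged and the fit restricted to the first
transition with a warning.

## Synthetic fixtures: what they do and do not show

The generators make the whole stack testable without downloads:

- `make_toy_structure()` builds an ideal α-helical backbone with C-beta
  stubs and places hetero atoms at exact distances from named atoms along
  the outward radial direction, so contact-detection tests have
  geometrically exact oracles. It emits standards-valid minimal mmCIF.
- `make_pseudo_residue_dataset()` gives each of the 20 classes a fixed,
  distinct atom motif (elements drawn from the channel-mapped set so the
  element channels carry the class signal; charge and SASA channels carry
  redundant signal to exercise them) and jitters coordinates with Gaussian
  noise (default σ = 0.3 Å). Real microenvironments are not this separable:
  passing the learnability bar (≥90% held-out accuracy) demonstrates that
  featurization, training and evaluation are wired correctly and can extract
  geometric/compositional signal — it says nothing about attainable accuracy
  on real structures, which requires PDB-scale data. The label-permutation
  control (accuracy ≈ 1/20) guards against leakage through the pipeline.
- `make_kinetics_curves()` reproduces the assay design the kinetics code
  targets — 3.5 nM enzyme, substrate at 15.625–500 µM in doublings, hourly
  sampling over 4 h, triplicate — with multiplicative Gaussian noise
  (default 2%).
- `make_mutation_table()` plants prediction profiles whose log-odds have a
  known correlation with synthetic ΔTm values, giving the benchmark an
  exact oracle.

All generators are pure functions of their parameters and seed.

## Problem sizes and reproducibility

The standard verification runs use: 2000 pseudo-residue grids (100 per
class) with a 90:10 split and a reduced network (one residual block, stem
width 16, ~74k parameters) trained 3 epochs at batch 50; 20 replicate
kinetic datasets at the full assay design with 9-point contour scans; and
dense noiseless curves for the Hill and Boltzmann recoveries. These sizes
make each analysis complete in minutes on a single core while leaving the
pass/fail margins wide. Every stochastic step — sampling, splitting,
initialization, shuffling, noise — flows from an explicit integer seed, and
repeated runs with the same seed are bit-identical.

## Known limitations

- The charge template is a neutral-sum simplification; ligand atoms have no
  lookup charges. External per-atom charge files are first-class input.
- The published full-scale results (≈80% wild-type accuracy on PDB-scale
  test sets, FireProtDB correlations) are out of desk-scale reach by
  design; the package exposes the code paths but validates them on
  synthetic fixtures.
- The network trains on CPU via BLAS; it is deliberately compact. Training
  thousands of epochs-scale workloads would need a GPU tensor backend,
  which is out of scope.
- Sequence-identity clustering of training chains is delegated upstream
  (structure selection), not reimplemented.
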