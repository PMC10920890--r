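# voxdesign

Structure-based protein engineering in R: voxelized residue
microenvironments, masked-residue prediction with a 3D residual network,
log-odds mutation scoring, and the downstream validation analyses —
mass-action enzyme kinetics with confidence contours, Hill dose-response
fits, and Boltzmann thermal-melt fits.

## Who this is for

Protein engineers and structural bioinformaticians who want a
self-contained, desk-scale implementation of the masked-residue design
loop: take a structure (with its ligands, cofactors, ions or nucleic
acids), ask "which amino acid does this neighbourhood expect?", and rank
substitutions where the model disagrees with the wild type. The same
package carries the wet-lab-facing statistics used to characterize the
resulting variants.

## The core method

For a residue with backbone atoms N, CA, C, the package builds a local
frame (origin at the C-alpha, +z toward the ideal-geometry virtual C-beta,
+x along the orthogonalized N−CA direction), collects all atoms within a
20 Å cube in that frame, removes the center residue's own atoms, and
renders the rest into a 20×20×20×9 tensor: seven element channels
(C, H, O, N, S, P, grouped halogens) plus partial-charge and SASA
channels, each atom Gaussian-blurred with σ = 0.5·r_vdW. A 3D residual
convolutional network maps the tensor to a 20-way softmax over amino-acid
identity. Candidate mutations are scored by the log-odds

    score(wt -> mut) = ln p(mut) − ln p(wt)

with positive scores read as favorable. Enzyme kinetics are fit globally to
progress curves under the mass-action scheme E+S→ES→EP→E+P (plus background
substrate oxidation S→P2, and a substrate-inhibition variant with SE/SES
species); under the standard locks, k₊₂ = kcat and k₊₁ = kcat/Km, with 95%
intervals from profile-χ² confidence contours thresholded by the
F-distribution. Dose-response curves use the Hill equation
y = d + (a−d)xᵇ/(cᵇ+xᵇ) (c = EC50); melts use the Boltzmann sigmoid
F = F_min + (F_max−F_min)/(1+exp((Tm−T)/slope)).

## Worked example

```r
library(voxdesign)

# a synthetic helix with a phosphorus "ligand" 4 A from residue 3
s <- make_toy_structure(8, placements = list(
  list(element = "P", residue = 3, distance = 4.0)))
s <- annotate_structure(s)   # template charges + Fibonacci-lattice SASA

find_interface_residues(s)
#> # A tibble: 1 × 5
#>   chain residue_seq insert residue_name interface_kind
#>   <chr>       <dbl> <chr>  <chr>        <chr>
#> 1 A               3 ""     ALA          ligand

env <- extract_microenvironment(s, "A", 3)
env
#> <microenvironment> toy A3 (ALA)
#>   atoms in 20 A cube: 36; interface: TRUE [ligand]
g <- voxelize(env)
dim(g)
#> [1] 20 20 20  9
```

The residue sits 4 Å from the ligand, so it is interface-flagged, its own
five atoms are masked out of the 41-atom structure, and the remaining 36
atoms render into the 9-channel tensor. Training and scoring run on the
synthetic 20-class dataset:

```r
ds <- make_pseudo_residue_dataset(100, noise_sigma = 0.3, seed = 11)
sp <- split_dataset(ds$grids, sampling_config(seed = 5),
                    interface_flags = rep(FALSE, length(ds)))
model <- build_model(model_config(n_residual_blocks = 1, base_width = 16, seed = 3))
run <- train_model(model, voxel_subset(ds, sp$train),
                   train_config(batch_size = 50, max_epochs = 3,
                                lr_decay_constant = 0.3, seed = 9),
                   heldout = voxel_subset(ds, sp$test))
dplyr::last(run$history$heldout_accuracy)
#> [1] 1
```

and the kinetics path recovers planted parameters from simulated progress
curves:

```r
scheme <- build_minimal_scheme()            # k_ox = 0.00547 min^-1 preset
d <- make_kinetics_curves(scheme, c(`k+1` = 1.18, `k+2` = 73),
                          noise_frac = 0.02, seed = 1)
fit <- fit_kinetics(scheme, d, sigma = 0.02 * pmax(d$product_uM, 1e-3))
fit
#> <kinetic_fit> scheme 'minimal': chisq_min = 59.8315 over 72 points
#>   k+1   = 1.18062
#>   k+2   = 73.325
#>   kcat = 73.33 min^-1, kcat/Km = 1.181 uM^-1 min^-1, Km = 62.11 uM
confidence_contour(fit, "k+2")
#> <confidence_contour> k+2 = 73.33
#>   95% CI: [72.36, 74.31]  (chisq ratio threshold 0.918)
derive_km(73, 1.18)
#> [1] 61.86441
```

Here kcat comes back within ~0.4% of the planted 73 min⁻¹, the contour CI
brackets the truth, and the Km implied by the canonical 73 / 1.18 division
rounds to 62 µM. Fitted objects have `tidy()`, `glance()` and `autoplot()`
methods; `inst/cli/voxdesign.R` exposes `prep`, `kinetics`, `hill` and
`melt` subcommands for shell use.

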