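---
title: "Deformable-registration-guided histogram matching for CBCT intensity correction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CBCT correction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cbcthm)
```

## The problem

Cone-beam CT (CBCT) acquired on the treatment machine guides adaptive
radiotherapy, but scattered radiation corrupts its Hounsfield units (HU):
a global bias, smooth shading/cupping fields, and elevated noise make CBCT
numbers unusable for dose calculation. A planning CT (pCT) of the same
patient carries trustworthy HU but outdated anatomy. `cbcthm` implements
the pCT-based correction workflow: align the pCT to the CBCT (rigid, then
deformable), and remap CBCT intensities so their cumulative distribution
matches the deformed pCT's. The package also ships the evaluation suite
used to quantify the correction and a synthetic pelvis phantom generator
that stands in for patient data, with a known ground-truth deformation and
artifact model.

## Workflow and models

### Preprocessing

The body is isolated by thresholding (default surface thresholds: -700 HU
for pCT, -600 HU for CBCT), morphological closing (ball radius 2 voxels),
retention of the largest 3D connected component (which removes couch
structures without manual cropping), and interior hole filling so gas
pockets stay inside the body. All exterior voxels are set to -1000 HU. The
operation is idempotent, and lowering the threshold can only grow the
mask.

Hole filling means the shipped mask is the filled body: interior air has
HU below the surface threshold yet belongs to the mask. The -1000 fill is
applied only outside that filled body.

### Similarity metrics

With fixed image $I_F$ (the CBCT), moving image $I_M$ (the pCT), and a
transform $T$ mapping fixed points into the moving image, metric
evaluation uses a sampling domain $\Omega_F$ of fixed-image sites
(restricted to the CBCT body mask; sites mapping outside the moving image
are dropped):

* **NCC** — Pearson correlation of $I_F(x_i)$ and $I_M(T(x_i))$ over
  $\Omega_F$, with both means taken over the same sites.
* **MI** — $H(I_F) + H(I_M) - H(I_F, I_M)$ with entropies in nats,
  estimated from a joint histogram over equal-width bins spanning each
  image's intensity range. During optimization the moving axis uses a
  cubic B-spline Parzen window (differentiable); the fixed axis is
  hard-binned. Hard binning on both axes is available for validation
  against direct counts.
* **NMI** — $(H(I_F) + H(I_M))/H(I_F, I_M)$, identically
  $1 + \mathrm{MI}/H_{joint}$.

The default histogram resolution is 64 bins per axis: with a soft-tissue
HU spread of a few tens of HU, 32 bins over the full CT range (~60 HU per
bin) cannot resolve the intensity texture that drives the deformable
alignment, while 64 bins can.

### Transforms

Rigid transforms rotate (Euler angles, $R_z R_y R_x$) about the
fixed-image centre and translate, in physical mm. The deformable stage is
a free-form deformation on a cubic B-spline control grid covering the
fixed image: final grid spacing 32 mm, refined dyadically over three
resolution levels (128, 64, 32 mm) with exact coefficient subdivision, so
each level starts from the previous level's field. The composite applies
the rigid stage first, then adds the B-spline displacement.

Control-point displacements are box-bounded at `grid_spacing / 2.48` per
axis, the classical sufficient condition for a fold-free (single-valued,
invertible) cubic FFD. This is a validity constraint, not a smoothness
penalty; bending-energy regularization is intentionally out of scope.

### Optimization

Each of three pyramid levels (downsampling 4, 2, 1; Gaussian smoothing 4,
2, 0.5 voxels) runs adaptive stochastic gradient ascent: at every
iteration a fresh set of sites is drawn uniformly inside the mask,
jittered off-grid (on-grid sites produce one-sided interpolation
gradients exactly at alignment, which biases the optimum), and the
analytic metric gradient with respect to the transform parameters drives
a normalized-gradient step of magnitude
$s_0 ((A+1)/(A+t))^{\alpha}$ with $A = 20$, $\alpha = 0.602$, and $s_0$
half a voxel (rigid: half the level voxel; B-spline: half the
full-resolution voxel, since control displacements live on the warp's own
scale). The artificial time $t$ advances through a sigmoid of the
negative inner product of successive gradients: agreement keeps steps
large, oscillation near the optimum decays them. 384 iterations and 4096
samples per iteration are the defaults.

Stochastic iterates hover around the optimum, so each level ends with a
deterministic quasi-Newton (L-BFGS-B) polish:

* the **rigid** stage polishes on a frozen set of 32768 jittered sites —
  six parameters cannot overfit such a set;
* the **B-spline** stage polishes on the complete population of
  fixed-image sites, split in half: L-BFGS runs on one half in short
  bursts while the metric on the held-out half decides when to stop
  (with a patience of three bursts). Early stopping is what keeps the
  several-thousand-parameter FFD from chasing the CBCT's own noise,
  which is part of the data and therefore not averaged away by fresh
  sampling.

The finest pyramid level keeps almost no smoothing (0.5 voxel): at the
phantom's coarse voxels (3.4-6 mm) a one-voxel blur removes most of the
correlated tissue texture that makes the deformable problem well-posed,
and recovery degrades severely.

### Histogram matching

Cumulative histograms (1024 equal-width bins over the union intensity
range) are built inside the shared body mask — background air at -1000
would otherwise dominate both CDFs and flatten the map. Each source level
maps to the smallest reference level whose cumulative value reaches the
source's, linearly interpolated between reference bin edges; the LUT is
monotone and is applied only to masked voxels. Matching is performed once,
in 3D, against the deformed pCT resampled onto the CBCT grid, so both
histograms sample the same field of view.

### Evaluation

* **Volume HU error** — RMS of the voxelwise HU difference over the
  evaluation mask (the intersection of the CBCT body mask and the
  deformed pCT's body support, all on the CBCT grid).
* **Binned MAE** — voxels grouped by reference (pCT) HU into 20-HU bins
  anchored at odd multiples of 10 around zero (centre $c$ collects
  $[c-10, c+10)$; boundary values go up). Each bin reports the mean
  absolute HU difference; empty bins report `NA`, never 0. Bin centres
  are annotated with tissue classes: air below -400 HU, soft tissue
  $[-400, 250)$, soft bone $[250, 600]$, bone above 600.
* **Spatial-uniformity RMSD** — mean HU over 10x10-pixel single-tissue
  ROI boxes; the cohort statistic is the RMSD across subjects of each
  subject's mean ROI value (reference vs test), one value per tissue per
  arm — the only aggregation that yields one RMSD per tissue per method
  column.

### The phantom

The package ships no patient data, so the generator emulates clinically
realistic conditions: a pelvis-like arrangement of parametric ellipsoids (muscle
body, subcutaneous fat layer, two interior fat pockets, two femoral-head
bone ellipsoids with soft-bone rims, a rectal gas pocket) at tissue means
air -1000, fat -100, muscle +50, soft bone +400, bone +900 HU — centred
in the tissue-class intervals above. Defaults: pCT grid 96x96x40 at
3.3984 x 3.3984 x 6 mm; CBCT spacing 3.5156 x 3.5156 x 5 mm covering the
central 40% of the axial extent. These preserve the clinical pCT/CBCT
anisotropy and slice-coverage ratios at four times coarser sampling, so a
full registration-correction-evaluation cycle runs in tens of seconds;
the vignette-scale problem sizes (5-subject cohorts, ~36k masked CBCT
voxels) are the package's chosen working point.

Two stochastic fields give the tissues their texture: iid per-voxel
jitter (sd 8 HU) and a smooth heterogeneity field (sd 25 HU, 12 mm
correlation length; reduced amplitude in bone, none in gas). The
heterogeneity field is a deliberate design element: real soft tissue
carries correlated structure (vessels, bowel, trabeculae) that deformable
registration tracks; with ellipsoid boundaries and iid jitter alone the
interior deformation is unobservable (an aperture problem — iid jitter
decorrelates under interpolation and CBCT noise), and no intensity-based
method could recover the warp the phantom is built to test.

The ground-truth deformation is a cubic B-spline field (48 mm control
spacing) with seeded random coefficients, zeroed within one grid spacing
of the volume boundary and rescaled so the dense-field maximum equals the
requested amplitude (default 8 mm, far below the fold-free limit; the
field's Jacobian determinant stays positive). The CBCT arm warps the pCT
onto the CBCT grid and applies, inside the body,
$v \mapsto v\,s(x) + b + \varepsilon$: a shading field $s$ (radial
cupping polynomial plus a seeded low-frequency cosine field, relative
amplitude 10%), global shift $b = -60$ HU, and Gaussian noise
$\varepsilon$ (sd 20 HU). Outside the body stays exactly -1000. Every
quantity is a pure function of the spec and its seed.

What the phantom does *not* emulate: projection-domain physics (no
Monte-Carlo scatter, no reconstruction artifacts such as streaks or
rings), organ sliding and topology changes, metal, or patient-realistic
shapes. Passing the package's tests therefore shows the pipeline recovers
smooth deformations and corrects smooth multiplicative/additive intensity
distortions at realistic magnitudes — not that it handles every clinical
failure mode.

## Worked example

```{r example}
library(cbcthm)

ph <- generate_phantom_pair(phantom_spec(seed = 1))
cfg <- pipeline_config(seed = 1)
res <- run_pair(cfg, ph$pct, ph$cbct, "DR-NCC",
                rois = c(place_rois(ph$cbct_labels, tissue_codes[["fat"]], 5),
                         place_rois(ph$cbct_labels, tissue_codes[["muscle"]], 5)))
res$report

# cohort-level comparison of all four arms
summary5 <- run_cohort(pipeline_config(seed = 1), n_subjects = 5)
summary5
```

## Numerical choices and degenerate inputs

* Entropies are in nats; NMI is base-invariant.
* Constant-valued samples raise a `"degenerate sample"` error in NCC (no
  variance) and NMI (zero joint entropy) instead of returning `NaN`; a
  constant image in a joint histogram is legal and yields a single-bin
  marginal with zero entropy.
* Histogram edge handling: values at the top edge fall in the last bin;
  Parzen kernel mass beyond the range is accumulated at the edge bins so
  the joint always normalizes to 1.
* CDF inversion breaks ties downward (smallest reference level), which
  with `cummax` guarantees a monotone LUT even across empty bins.
* Interpolation outside the moving image returns the fill value
  (-1000 HU) for resampling, while metric evaluation drops such sites.
* All randomness flows from one integer seed through labelled derived
  seeds (`derive_seed`), so adding an algorithm arm never shifts another
  arm's stream, and repeated runs are bit-identical.

## Known limitations

* The global NCC of the similarity stage is not invariant to the
  spatially varying shading field; on phantoms with strong cupping the
  NCC arm converges slightly less tightly than MI/NMI, consistent with
  the metric's model.
* Recovery of the deformation near the CBCT's axial boundary slices is
  intrinsically weaker (one-sided data support); residual displacement
  errors concentrate there.
* Unregularized FFDs plus noisy targets are ill-posed at fine grid
  spacings; the fold-free bound and validated early stopping contain but
  do not eliminate noise-chasing. A bending-energy penalty would be the
  natural extension and is deliberately not included.
* Histogram matching is global and monotone: it cannot repair spatially
  varying residual shading, only redistribute intensities; what remains
  after correction is dominated by noise and local misalignment at
  tissue interfaces.
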