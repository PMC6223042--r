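# cbcthm

Intensity correction of cone-beam CT (CBCT) for adaptive radiotherapy,
guided by deformable registration to the planning CT (pCT).

CBCT volumes acquired on the treatment machine carry heavily distorted
Hounsfield units — a global bias, smooth shading/cupping fields from
scattered radiation, and elevated noise — which makes them unusable for
dose calculation even though their anatomy is current. `cbcthm`
implements the pCT-based correction workflow used in radiotherapy
physics, entirely in R (with an Rcpp numerical core):

1. **Preprocessing** — automatic body-mask extraction (surface threshold
   −700 HU for pCT, −600 HU for CBCT; morphological closing; largest
   3D component; hole filling) and −1000 HU background fill.
2. **Rigid pre-alignment** — 6-DOF registration of the pCT to the CBCT
   maximizing mutual information.
3. **Deformable registration (DR)** — multi-resolution (3-level) cubic
   B-spline free-form deformation under one of three similarity metrics,
   optimized by adaptive stochastic gradient descent (ASGD) with a
   deterministic quasi-Newton polish per level:
   - NCC, the normalized correlation coefficient
     `NCC = Σ(I_F − Ī_F)(I_M∘T − Ī_M) / sqrt(Σ(I_F − Ī_F)² Σ(I_M∘T − Ī_M)²)`
   - MI, mutual information `MI = H(I_F) + H(I_M) − H(I_F, I_M)`
   - NMI, normalized mutual information
     `NMI = (H(I_F) + H(I_M)) / H(I_F, I_M) = 1 + MI / H(I_F, I_M)`
4. **Histogram matching (HM)** — each CBCT intensity is replaced by the
   HU with the same cumulative value in the deformed pCT
   (`CBCT(H₁) = pCT(H₂)` on the matched cumulative histograms), via a
   monotone piecewise-linear lookup table restricted to the body mask.
5. **Evaluation** — volume HU error
   `V_err = sqrt(mean[(HU_pCT − HU_CBCT)²])`, mean absolute error in
   20-HU bins of reference HU annotated by tissue class (air < −400,
   soft tissue [−400, 250), soft bone [250, 600], bone > 600), and
   spatial-uniformity RMSD of mean HU over 10×10-pixel same-tissue ROIs.

Four algorithm arms are compared: rigid-only **RR-MI**, and **DR-NCC**,
**DR-MI**, **DR-NMI** — the rigid arm is kept to show how much of the
correction quality depends on resolving the anatomical deformation.

Because no patient data are distributed, the package includes a
first-class synthetic pelvis phantom generator (`phantom_spec()`,
`generate_phantom_pair()`): paired pCT/CBCT volumes with realistic
tissue HU, correlated soft-tissue texture, a known fold-free B-spline
ground-truth deformation, and a CBCT artifact model (−60 HU shift, 10%
shading, 20 HU noise, reduced axial coverage, its own voxel spacing).
Every stage is a pure function of one integer seed.

## Worked example

```r
library(cbcthm)

ph  <- generate_phantom_pair(phantom_spec(seed = 1))   # pCT + degraded CBCT
cfg <- pipeline_config(seed = 1)
res <- run_pair(cfg, ph$pct, ph$cbct, "DR-NCC",
                rois = c(place_rois(ph$cbct_labels, tissue_codes[["fat"]], 5),
                         place_rois(ph$cbct_labels, tissue_codes[["muscle"]], 5)))
res$report
#> <evaluation_report> DR-NCC
#>   V_err before HM: 67.53 HU, after HM: 19.26 HU
#>   MAE bins: 99 before, 99 after; ROIs: 10
```

`V_err before HM` is the RMS HU disagreement between the deformed pCT
and the raw CBCT (dominated by the −60 HU bias, shading and noise);
`after HM` is what remains once the CBCT histogram has been matched to
the deformed pCT — mostly noise plus interface misalignment. A cohort
across all four arms reproduces the expected ordering (deformable arms
correct much better than rigid-only; fat/muscle uniformity collapses to
a few HU):

```r
run_cohort(pipeline_config(seed = 1), n_subjects = 5)
#> <cohort_summary> 5 subject(s), seed 1
#> Volume HU error (mean +- sd across subjects):
#>   DR-MI   before HM  69.40 +-  1.58   after HM  26.85 +-  2.17
#>   DR-NCC  before HM  67.21 +-  0.85   after HM  19.49 +-  0.28
#>   DR-NMI  before HM  67.40 +-  1.11   after HM  20.03 +-  0.85
#>   RR-MI   before HM  99.77 +-  6.12   after HM  75.04 +-  5.38
#> ROI uniformity RMSD (HU):
#>   DR-MI   fat         before  56.78   after   2.72
#>   DR-NCC  fat         before  56.86   after   3.35
#>   DR-NMI  fat         before  56.94   after   3.30
#>   RR-MI   fat         before  59.73   after   1.60
#>   DR-MI   muscle      before  62.40   after   1.93
#>   DR-NCC  muscle      before  61.92   after   1.82
#>   DR-NMI  muscle      before  62.04   after   1.93
#>   RR-MI   muscle      before  61.90   after   1.99
```

A thin command-line wrapper over the same functions lives at
`inst/cli/cbcthm.R` (subcommands `phantom`, `preprocess`, `register`,
`histmatch`, `evaluate`, `run`).

See the vignette (`vignettes/cbct-correction-methods.Rmd`) for the
models, parameter choices and known limitations.

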