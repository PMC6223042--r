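Package: cbcthm
Title: Histogram-Matching Correction of Cone-Beam CT Guided by Deformable Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Intensity correction of cone-beam CT (CBCT) volumes for adaptive
    radiotherapy. The planning CT is aligned to the CBCT by rigid
    mutual-information registration followed by multi-resolution cubic
    B-spline deformable registration under a choice of similarity metric
    (normalized cross-correlation, mutual information, or normalized mutual
    information), optimized by adaptive stochastic gradient descent; CBCT
    Hounsfield units are then corrected by cumulative-histogram matching
    against the deformed planning CT. Includes automatic body-mask
    preprocessing, a synthetic pelvis phantom generator with known
    ground-truth deformation and CBCT artifact fields, and a quantitative
    evaluation suite (volume RMS HU error, mean absolute error binned by
    tissue class, and ROI spatial-uniformity RMSD).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
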