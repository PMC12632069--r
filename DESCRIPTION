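Package: logdoseqa
Title: Log-File-Based 3D Dose Reconstruction and Patient-Specific QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of intensity-modulated
    radiotherapy (IMRT) from accelerator delivery logs. Parses step-and-shoot
    delivery records (MLC leaf positions, cumulative monitor units, gantry
    angles), reconstructs MU-weighted 2D fluence maps in the beam's eye view,
    projects them through the patient voxel grid with a 3D digital differential
    analyzer (3D-DDA) ray traversal under inverse-square attenuation, and
    assembles co-registered model samples (CT, structure masks, projected
    volume, reference dose) on a common cubic grid. Includes a group-supervised
    encoder-decoder dose-prediction network with a desk-scale CPU trainer,
    a deterministic synthetic thoracic phantom generator, and quantitative
    dose-comparison metrics: per-ROI MAE/RMSE, DVH indices (D95/D98/D99/Dmax/
    Dmean, V5/V20/V30/V40, mean lung/heart dose), isodose Dice curves, dose
    profiles and Bland-Altman agreement limits.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
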