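Package: qsmadapt
Title: Adaptive-Convolution Deep Learning for Quantitative Susceptibility Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Field-to-susceptibility inversion for quantitative susceptibility
    mapping (QSM) with a 3D U-Net whose first-stage convolution weights are
    generated by a filter-manifold network from acquisition side information
    (voxel size and B0 orientation). Includes the k-space dipole forward model
    for arbitrary voxel sizes and tilted fields of view, a synthetic
    susceptibility phantom generator producing paired field/susceptibility
    training scenes, a physics-consistent training loss with AdamW and
    cosine-annealing warm restarts, transfer learning with frozen adaptive
    layers, and evaluation metrics (NRMSE, SSIM, PSNR, seeded scatter
    regression, region statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
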