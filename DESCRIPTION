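Package: sisr
Title: Super-Resolution Reconstruction of MR Spectroscopic Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes paired low- and high-resolution magnetic resonance
    spectroscopic imaging (MRSI) metabolite maps from T1-weighted brain
    images (real or phantom), and reconstructs super-resolution metabolite
    maps from the pair (T1w image, nearest-neighbor-upscaled low-resolution
    map) with a densely connected U-Net trained on a stream of freshly
    generated cases. Includes k-space truncation and zero-filling
    interpolation, bicubic baselines, a parametric Lorentzian spectral
    simulator for point-by-point spectral super-resolution, noise-robustness
    sweeps, and metabolite-ratio analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
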