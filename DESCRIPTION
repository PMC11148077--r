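Package: idcwm
Title: Covariance of Isodendritic-Core Nucleus Microstructure with
    White-Matter NODDI Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements, at desk scale, a quantitative-MRI analysis
    pipeline linking the microstructure of four neuromodulatory
    (isodendritic-core) nuclei -- locus coeruleus, dorsal raphe, ventral
    tegmental area and nucleus basalis of Meynert, measured by
    multiparametric mapping (R1, MTsat, R2*, PD) -- to whole-brain
    white-matter microstructure measured by NODDI (NDI, ODI, FW).
    Includes a seeded synthetic phantom generator with planted latent
    covariance, multi-echo FLASH and multi-shell DWI signal simulators,
    ESTATICS-style joint R2* estimation with double-angle B1 correction,
    a Watson-dispersion NODDI forward model with a dictionary/NNLS
    fitter, ROI and voxel-dataset preparation (probabilistic-mask
    thresholds, confound residualization, masked Gaussian smoothing),
    multi-condition behavioral partial-least-squares correlation with
    permutation and procrustes-aligned bootstrap inference, bootstrap-
    ratio cluster filtering, and downstream biomarker regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
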