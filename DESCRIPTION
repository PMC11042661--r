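Package: slicestress
Title: Residual Solid Stress Mapping and Viscoelastic Analysis of Tissue Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies residual solid stress in soft tissue from the
    deformation of thin slices cut free of their surroundings. Reconstructs
    the relaxed slice surface as a height field from 3D fluorescence stacks
    and computes three stress indices: normalized deformation (mean absolute
    height deviation), area ratio (curved over projected surface area), and
    the mean-curvature index (average absolute Monge-patch mean curvature),
    together with per-pixel deformation and curvature maps. Also analyzes
    step-hold unconfined-compression data: stress and strain conversion,
    ramp segmentation, Young's modulus from the linear stress-strain fit,
    the instantaneous/equilibrium modulus ratio, and bi-exponential
    stress-relaxation fitting. Includes a synthetic-data generator producing
    image stacks of analytically known surfaces and force traces with known
    mechanical parameters, plus group-comparison and spatial-trend
    statistics and a report builder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
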