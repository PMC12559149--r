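Package: torsionlab
Title: Femoral and Tibial Torsion Quantification from Axial MRI with
    k-Space Artifact Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for studying the robustness of automated
    lower-limb torsion measurement to MRI motion artifacts. Generates
    synthetic axial image stacks of the hip, knee, and ankle with known
    ground-truth torsion angles; corrupts them with k-space artifact
    operators (ghosting, spiking, segment-wise motion) and intensity
    artifacts at graded severity; segments bone with a deterministic
    threshold-morphology stand-in segmenter; quantifies femoral torsion by
    the Lee method (least-squares circle fits of femoral head and neck,
    posterior condylar tangent) and tibial torsion by the Ulm method
    (posterior tibial tangent, distal tibio-fibular centroid axis); and
    evaluates agreement with Dice coefficients, mean absolute deviation,
    intraclass correlation, repeated-measures ANOVA with Tukey HSD, and
    linear mixed-effects models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    withr,
    jsonlite,
    yaml,
    RNifti,
    EBImage,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
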