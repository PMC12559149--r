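# torsionlab

Quantifying femoral and tibial torsion from axial lower-limb MRI is a
segmentation-plus-geometry problem: segment the bones on a few axial
slices, construct reference lines from landmarks, report the angle
between them. Motion artifacts — ghosting, spiking, blurring,
segment-wise k-space inconsistency — corrupt the segmentation and
thereby the angles. `torsionlab` is a desk-scale R implementation of
that entire measurement chain on synthetic phantoms with *known* ground
truth, so that the robustness of the chain to graded artifact severity
can be measured rather than asserted.

It is aimed at researchers building or evaluating automated
torsion-measurement pipelines who need a controlled testbed: every
stage is seeded, every landmark is known in closed form, and every
reported number is recomputable.

## What it implements

**Geometry.** Femoral torsion by the Lee construction: the angle
between the neck axis — through the least-squares circle centres of the
femoral head and neck — and the posterior condylar tangent. Tibial
torsion by the Ulm construction: the angle between the posterior
tibial-plateau tangent and the line through the centroids of the distal
tibia and fibula. Angles are undirected line angles in (−90°, 90°],
positive = anteversion, left limbs mirrored in x so the convention is
bilateral. The posterior tangent is the posterior convex-hull edge
spanning both condylar lobes — equivalent to advancing a line
anteriorly until first contact.

**Artifact simulation.** k-space operators (ghosting = periodic
phase-encode line attenuation; spiking = Hermitian point insertion;
motion = line-wise assembly from rigidly transformed states) plus blur,
polynomial bias field, and noise, wrapped in a probabilistic sampler
(each artifact with probability 0.5, spikes 0.02) with
`none/mild/moderate/severe` severity presets.

**Phantoms.** Hip, knee, and ankle stacks per limb with femur, tibia,
and fibula label maps, anisotropic spacing, T2-like contrast, and a
ground-truth record of every landmark, reference line, and torsion
angle.

**Evaluation.** A threshold-morphology stand-in segmenter, Dice
coefficients, slice-wise mutual-information similarity registration for
motion-displaced ankle stacks, and the statistical layer: MAD, ICC(2,1)
with F-bound CIs, Pearson r, repeated-measures ANOVA with Tukey HSD,
random-intercept linear mixed models (lme4/lmerTest), and an a-priori
sample-size calculator for within-subject designs.

## Worked example

```r
library(torsionlab)

limb <- generate_limb(limb_spec(femoral_torsion_deg = 15,
                                tibial_torsion_deg = 35))
res <- measure_limb(limb$hip$labels, limb$knee$labels, limb$ankle$labels)
res
#> <torsion_result> success=TRUE femoral=14.99 tibial=34.94
```

The phantom was built with 15° femoral and 35° tibial torsion; the
chain recovers 14.99° and 34.94° from the rasterized label maps at
0.6 mm in-plane spacing — the residual is raster quantization.

Corrupt the ankle stack with severe slice-wise motion (the
through-plane misalignment foot motion produces) and the measurement
degrades:

```r
corr <- sample_mri_specific(limb$ankle$image, limb$ankle$labels,
                            severity_to_params("severe", slice_wise = TRUE),
                            seed = 3)
seg <- segment_stack(corr$image)
dice(seg, corr$labels, label_code = 2)          # tibia overlap
#> [1] 0.794
tibial_torsion(limb$knee$labels, seg)$angle     # truth is 35
#> [1] 29.04
dice(segment_stack(limb$ankle$image), limb$ankle$labels, label_code = 2)
#> [1] 1
```

The corrupted stack loses a fifth of its tibial overlap and six degrees
of torsion accuracy; the clean stack segments almost perfectly.

A full experiment — cohort generation, corruption at four severities,
segmentation, torsion measurement, summary tables, and a mixed model of
DSC on region + severity with a participant random intercept:

```r
bundle <- run_experiment(experiment_config(n_participants = 20, seed = 1))
bundle$success_table
bundle$angle_table
bundle$lmm$coefficients[["severitysevere"]]
```

A thin command-line wrapper lives in `inst/cli/torsionlab.R`
(`phantom`, `corrupt`, `segment`, `dice`, `measure`, `run-all`
subcommands over NIfTI files).

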