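# mpMRIseg

Semi-automatic rectal-tumor segmentation from multiparametric MRI by
voxelwise machine learning, for researchers studying how anatomical and
functional MR sequences combine for tumor volume definition (radiotherapy
planning, quantitative imaging biomarkers).

The pipeline treats segmentation as two-class voxel classification. One
patient study holds four sequences: anatomical T2-weighted (T2w), five-echo
T2\*-weighted (T2\*w), seven-b-value diffusion-weighted (DW, signal
`S0 exp(-b·ADC)`) and a dynamic multi-echo contrast series (DME, three
echoes per time point). Processing follows five stages:

1. **Preprocess** — select 14 dynamic time points (nearest to
   `t0 + 0, 4, …, 28 s`, then `t0 + 108, 188, …, 508 s` after contrast
   arrival `t0`), rigidly register all sequences to the T2w reference
   (6-DOF, histogram mutual information) and resample to a 1 mm³ grid
   cropped to a 20 mm margin around the union of two observer delineations.
2. **Features** — per voxel: 9 sorted in-plane T2w neighbours, 5 T2\*w
   echoes, 7 DW b-values, 42 DME intensities (63 in total); z-scored per
   image channel and patient.
3. **Classify** — LDA, QDA, linear SVM or AdaBoost (decision stumps, 100
   rounds) trained on per-patient class-balanced matrices (random
   undersampling), evaluated under patient-level leave-one-out
   cross-validation (LOO-CV).
4. **Post-process** — 3×3×3 median filter, watershed on the Euclidean
   distance transform, then keep only regions containing simulated seeds
   (one per axial slice of the ground truth): `final ⊆ smoothed prediction`.
5. **Evaluate** — Dice `2|P∩G|/(|P|+|G|)` and mean symmetric surface
   distance `MSD = (Σ d_i(G→P) + Σ d_i(P→G)) / (N_G + N_P)` in mm, with
   Friedman / Wilcoxon signed-rank / Bonferroni statistics for comparing
   algorithms and feature sets; results summarized as median [IQR].

Because clinical multiparametric rectal MRI is not public, the package
includes a first-class synthetic phantom generator (`phantomSpec()`,
`generateStudy()`) reproducing the acquisition grids of the clinical
protocol, closed-form sequence signals, per-sequence rigid misalignment,
noise, and two simulated observers calibrated to an interobserver Dice of
about 0.82. All experiments run end-to-end on phantom cohorts.

## Worked example

```r
library(mpMRIseg)

spec <- phantomSpec(gridScale = 2.5, zFovMm = 66,
                    tumorSemiAxes = c(12, 10, 9))
study <- generateStudy(spec, seed = 7, patientId = "P01")
study
#> MultiSequenceStudy 'P01'
#>   T2w 102x102x24 | 5 T2*w echoes | 7 DW b-values | 192 DME volumes
#>   truth mask: 2266 voxels; observers: 2548 / 2768 voxels

gt  <- groundTruthUnion(study@observerA, study@observerB)
box <- computeBoundingBox(gt, marginMm = 20, fov = commonFov(study))
pre <- registerAndResample(study, box)

fm  <- zscoreNormalize(assembleMatrix(pre, c("T2w", "T2sw", "DW", "DME")))
bal <- undersample(fm, seed = 5)
model <- trainClassifier(classifierKind("ADA"), list(bal))
raw  <- predictVolume(model, pre, matrix = fm)

gtIso <- groundTruthUnion(pre@observerA, pre@observerB)
res <- postProcess(raw, gtIso, seed = 11)
c(dice = dice(res@final, gtIso), msd = msd(res@final, gtIso))
#>      dice       msd
#> 0.8663043 0.8927934
```

The Dice of 0.87 says the post-processed mask captures most of the union
ground truth at the phantom's default contrast, noise and 3 mm observer
variation; the MSD of 0.89 mm says the two surfaces sit under a voxel apart
on average. (Training and predicting on the same phantom is only a smoke
test; use `looCv()` or the experiment drivers for honest estimates.)

Cohort experiments:

```r
cfg <- experimentConfig(nPatients = 8, spec = spec, masterSeed = 1,
                        kinds = list("LDA", "QDA", "SVM", "ADA"),
                        descriptors = allDescriptors())
tabAlg <- runAlgorithmComparison(cfg)   # four classifiers on T2w features
tabSet <- runFeaturesetComparison(cfg)  # 15 feature sets vs the T2w reference
writeReport(tabSet, "results/featureset", cfg, "featureset")
```

`writeReport()` stores per-patient metrics, the comparison table, and a
manifest with every seed; `runFromManifest()` reproduces the CSVs
bit-for-bit.

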