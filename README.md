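# cytoploidy

DNA ploidy analysis by image cytometry (ICM), calibrated against flow
cytometry (FCM).

Cytology labs quantify cellular DNA content to identify ploidy
populations — the diagnostic backbone of many cancer workups. Flow
cytometry is the reference method but consumes the sample; image
cytometry measures the same biology on digitized slides of
propidium-iodide (PI) stained nuclei, which can be stored and
re-analyzed. Before ICM measurements can be read on the FCM scale, the
two instruments must be calibrated against each other. Healthy blood is
a natural calibrator: it contains two nucleus populations whose DNA
contents sit in an exact 1:2 relation (the 2N/G1 and 4N/G2–M peaks), so
the 4N/2N peak ratio has a known theoretical value of 2.0 on *any*
correctly linear intensity scale.

This package implements the full analysis chain for that calibration,
plus a synthetic paired-data generator with known ground truth so every
stage is testable end to end:

1. **Per-nucleus features** (`extractFeatures`): DNA content as the
   background-corrected integrated optical density
   `IOD = Σ_{p∈O} I(p) − |O| · mean(B)`, where the background set `B`
   contains the unlabeled pixels at Euclidean distance in `(d, D]` from
   the object (defaults `D = 35`, `d = 5` px) and farther than `d` from
   *every* object; pixel-count area (the FSC-area analogue); and
   granularity (the SSC analogue) as the summed gradient magnitude over
   the eroded object interior, under five candidate operators (discrete
   morphological gradient, Roberts, Prewitt, Sobel, Canny).
2. **Operator selection** (`scoreOperators`): per-sample cluster-count
   estimation by the gap statistic in the (area, granularity) plane and
   majority-vote fault counting across operators.
3. **PCA denoising** (`fitPloidyPca`, `pcaCorrect`): per-sample
   covariance PCA of (area, DNA, granularity) verifying the
   near-independence of the three measurements and yielding
   noise-filtered coordinates.
4. **Population identification** (`fuzzyCMeans`, `filterUncertain`,
   `labelPopulations`): fuzzy c-means with `c = 3` (debris / 2N / 4N),
   membership-threshold uncertainty filtering, DNA-ordered labeling
   with a 4N/2N center-ratio sanity check.
5. **Peak estimation** (`histogramPeak`, `fitNormalPeak`): modal
   histogram bin and least-squares Gaussian fit
   `A · exp(−(x−μ)²/2σ²)` per population, applied identically to ICM
   and FCM values.
6. **Calibration** (`calibrateCohort`): per-sample least-squares scale
   through the origin, its naive cohort mean, pooled linear regression
   `fcm = a · icm + b` with RMSE/R²/Shapiro–Wilk residual diagnostics,
   and automatic low-intensity outlier flagging (modified z-score of
   log 2N peaks).

## Worked example

```r
library(cytoploidy)

cohort <- generateCohort(
  17,
  sampleSpec(nCells = 2000, cv = 0.03, frac4N = 0.25,
             fracDebris = 0.1, seed = 7))
report <- runPipeline(cohort)
report
```

```
ploidyRunReport: 17 of 17 samples analyzed
peak-ratio statistics (theoretical ratio: 2.0):
  method     mean          sd  n
 fcm_bin 2.007329 0.019082424 17
 icm_bin 1.995049 0.029092547 17
 icm_fit 2.000853 0.005750107 17
naive ICM->FCM scale: 0.00997922 (SD 9.2917e-05 )
regression (all samples):
  method      slope intercept      rmse r_squared  shapiro_p
 icm_bin 0.01006107 -5.489292 11.056870 0.9980561 0.01372294
 icm_fit 0.01001720 -3.173377  7.814203 0.9990291 0.05876718
```

Reading the output: all three peak-ratio variants recover the
theoretical 2.0 within sampling noise, and the Gaussian-fit ICM ratio
(`icm_fit`) has a markedly lower cohort SD than the modal-bin ratio
(`icm_bin`) — the reason the fitted peak is the preferred estimator.
The generator built this cohort with `fcmScale = 0.01` and
`icmScale = 1`, so the recovered naive scale and regression slope
(≈ 0.01) match the generative transfer scale, with R² ≈ 0.999 on this
homogeneous cohort. When per-sample intensity heterogeneity and
low-intensity outlier samples are simulated instead
(`icmScaleJitter`, `outlierIndices`), the pooled regression degrades
and its residuals turn non-normal — the regime in which a single linear
transfer function is not attainable.

Image-side measurement works the same way from rasters:

```r
g <- generateImageSample(sampleSpec(nCells = 8, seed = 5),
                         imageSceneSpec(imageSize = c(400, 400)))
ft <- extractFeatures(g$image, backgroundConfig(D = 35, d = 5))
head(ft[, c("object_id", "area_px", "iod", "gran_dmg")])
```

## Scope

Nucleus segmentation is out of scope: labeled masks are consumed, not
produced. There is no S-phase/cell-cycle deconvolution, no doublet
modeling, and no dye-bleaching compensation; transfer functions are
linear only. See the methods vignette (`vignettes/ploidy-calibration.Rmd`)
for the model, parameter defaults, and design rationale.
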