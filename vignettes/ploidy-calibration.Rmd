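---
title: "Methods: image-cytometry ploidy analysis and its calibration against flow cytometry"
author: "cytoploidy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-cytometry ploidy analysis and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoploidy)
```

## The measurement model

Propidium iodide binds DNA stoichiometrically, so under fixed exposure
the fluorescence collected over a nucleus is proportional to its DNA
content. On a digitized slide the package therefore measures DNA
content as the **integrated optical density (IOD)** of each labeled
object: the sum of the object's pixel intensities minus its pixel count
times a local background estimate,

$$\mathrm{IOD} = \sum_{p \in O} I(p) \;-\; |O| \cdot \overline{B}.$$

The background mean $\overline{B}$ is taken over the pixels that belong
to no object, lie within Euclidean distance $D$ of the measured object,
and are farther than $d$ from **every** object. Restricting the far
bound ($D$, default 35 px, about one object diameter at the working
magnification) keeps the estimate local, because dye accumulation and
illumination produce spatially varying background; the near bound
($d$, default 5 px) removes the halo in which an object's own glow (or
a neighbour's) contaminates "background" pixels. Extending the
$d$-exclusion to all objects, not only the measured one, is deliberate:
the point of the halo is that object proximity must not bias intensity
values, and a neighbouring nucleus biases them just as much as the
measured one. Distances are Euclidean, computed exactly in integer
squared-distance arithmetic against each object's 4-connected boundary
pixels (the nearest object pixel to any outside point is always such a
boundary pixel, so this is lossless). IOD may legitimately be negative
for a dim object on a bright background and is not clipped. When an
object's annulus is empty (an object fully enclosed by others), the
frame-global background (all unlabeled pixels farther than $d$ from
any object) is substituted and the event is reported as a warning and
in the feature table's `status` column.

Two invariances characterize a correct implementation and are enforced
by the test suite: adding a constant to every pixel leaves IOD
unchanged (the object sum gains $|O|c$, the background mean gains $c$),
and scaling all pixels by $\alpha$ scales IOD by $\alpha$ (linear
detector response).

**Area** is the exact pixel count of the label — the image analogue of
the FSC-area size signal. **Granularity** models the FCM side-scatter
(SSC) signal, which integrates internal optical complexity. It is
computed as the sum of a gradient-magnitude image over the object after
eroding the object mask by the operator's kernel radius: the sum (not
the mean) mirrors SSC's integral character, and the erosion suppresses
the strong object/background boundary edge so the value reflects
internal texture rather than perimeter. Five operators are provided:
the discrete morphological gradient (3×3 dilation minus erosion),
Roberts, Prewitt and Sobel gradient magnitudes, and a Canny binary edge
map. Canny needs parameters the operators' common description does not
fix; the package uses Gaussian smoothing with $\sigma = 1$, a high
hysteresis threshold from Otsu's criterion on the gradient magnitude,
and a low threshold at 0.4 of the high one. Whether granularity should
be computed on raw or background-subtracted intensities is
underdetermined; raw is used, since the linear gradient operators are
shift-invariant anyway.

## Choosing the granularity operator

The operator is selected empirically, per cohort: for every sample and
operator, the best cluster count in the standardized
(area, granularity) plane is estimated with the gap statistic
(`gapStatistic`), and an operator whose count disagrees with the
per-sample majority vote across operators incurs a fault
(`majorityScore`). The operator with the highest match ratio wins; ties
fall to the fixed precedence DMG > Prewitt > Roberts > Sobel > Canny,
reflecting that the morphological gradient and Prewitt are the
best-behaved candidates on this kind of data.

The gap statistic compares $\log W_k$ (within-cluster dispersion of
seeded k-means, k-means++ initialization, 10 restarts) against $B = 50$
reference sets drawn uniformly over the data's bounding box, and picks
the smallest $k$ with $\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) -
s_{k+1}$ (the one-standard-error rule). The evaluated range is
$k = 1..6$: three genuine populations (debris, 2N, 4N) plus headroom to
detect over-splitting operators. Both axes are standardized to unit
variance before clustering because area and granularity have
incomparable units. Majority ties resolve toward the smallest count
(the conservative reading) and are logged.

## PCA denoising and the scaling question

A per-sample PCA of (area, DNA content, granularity) serves two
purposes: it verifies that the three constructed measurements are
nearly independent (each principal component should be dominated by one
feature), and its scores provide noise-filtered coordinates for
population identification (`pcaCorrect` maps each feature to the score
of the component it dominates, rescaled to original units).

The default is **covariance PCA on the raw scales**
(`scaling = "none"`), and this choice is load-bearing. The three
measurements live on naturally separated scales (IOD in the tens of
thousands, granularity in the thousands, area in the hundreds), so
when cross-correlations are small each eigenvector locks onto one
feature and the loading matrix is near-axis, which is exactly the
structure that certifies independence. Unit-variance scaling destroys
this diagnostic: for any weakly coupled pair of standardized variables
the correlation-matrix eigenvectors sit at 45°
(the eigenvectors of $\bigl(\begin{smallmatrix}1&\rho\\\rho&1
\end{smallmatrix}\bigr)$ are $(1,\pm 1)/\sqrt2$ for every
$\rho \neq 0$), so dominant loadings saturate near $0.707$ no matter
how independent the data are. Unit-variance mode is retained as an
option for exploratory use. Component signs follow the convention that
each column's largest-magnitude loading is positive, making results
deterministic; components are identified by dominant loading rather
than by index, so the mapping is robust to eigenvalue ordering.

## Population identification

Populations are identified by **fuzzy c-means** (Bezdek alternating
optimization) with $c = 3$ — debris, 2N, 4N — on the denoised
(area, DNA) plane, followed by classification-uncertainty filtering:
an object is kept only if its maximum membership reaches the threshold
(default 0.6, configurable; the maximum membership is used as the
uncertainty measure, with the margin and entropy alternatives left to
the caller since the choice is underdetermined). The fuzzifier is the
standard $m = 2$; iteration stops when the largest center shift falls
below `tol` (default $10^{-5}$), interpreted **relative to the
root-mean-square spread of the data** so that the stopping rule does
not depend on measurement units. A point coinciding with a center
receives membership 1 there (the defined limit of the update rule).
Initialization picks data points by the k-means++ rule under a fixed
seed, so clustering is deterministic.

Clustering runs on the raw denoised coordinates, not standardized
ones. This is intentional: DNA content is the discriminative axis and
is orders of magnitude wider than area, so the metric is effectively
DNA-led, matching how the populations present in the component-plane
scatterplots. Standardizing the axes was evaluated and rejected — it
lets the soft memberships of the (small) debris cluster drag its center
toward the data bulk along the area axis, which then captures
low-area 2N nuclei; on ground-truth cohorts this costs about 5% label
accuracy, while DNA-led clustering recovers essentially all non-debris
labels.

Clusters are labeled by ascending DNA center as debris / 2N / 4N, and a
sample whose 4N/2N center ratio falls outside $[1.5, 2.5]$ is flagged
as mis-clustered and quarantined by the pipeline rather than silently
mislabeled.

## Peak estimation

Each population's DNA peak is estimated two ways. The **modal-bin**
estimate is the center of the highest histogram bin (256 half-open
bins over the sample's DNA range by default — an FCM-like channel
resolution; ties resolve toward the lower bin and are logged). The
**Gaussian-fit** estimate least-squares fits
$A\exp(-(x-\mu)^2/2\sigma^2)$ to the population's binned counts
(Levenberg–Marquardt, initialized at the modal bin and the sample SD)
and reports $\mu$. On non-convergence the estimate falls back to the
inner-90% trimmed mean and is flagged. Fits are computed over the
population's cluster members only, and the identical machinery serves
the FCM events (gated by the same c-means stage run on the 1-D channel
values), so both modalities are peak-estimated identically.

The modal bin is quantization-limited (bin width ≈ 0.4% of the data
range), while the fitted mean pools the whole population; across
seeded synthetic cohorts the SD of the fitted-peak 4N/2N ratio is
consistently below the modal-bin ratio SD, which is why the fitted
peak is the preferred estimator.

## Calibration

For each sample the ICM→FCM scale is the least-squares scale through
the origin over its two peaks,
$s = (f_2 i_2 + f_4 i_4)/(i_2^2 + i_4^2)$. The **naive transfer** is
the arithmetic mean of the per-sample scales (with its SD as the
honesty metric). The **regression transfer** pools both peaks of every
sample as separate points (2 points per sample; a 2N-only mode is
available for workflows that prioritize the 2N anchor) and fits
ordinary least squares with RMSE $= \sqrt{\sum r^2 / n}$, $R^2$, and a
Shapiro–Wilk test on the residuals — chosen as the standard omnibus
normality test at these sample sizes.

Low-intensity outlier samples (bleached or mis-exposed slides) are
flagged automatically: modified z-score (median/MAD) of the log 2N
peak below −3.5. The MAD is floored at 0.02 log units so that in very
homogeneous cohorts sub-percent sampling fluctuations can never
trigger a flag — a genuine outlier is a gross (≥ ~10%) intensity drop.
A manual exclusion list can augment the flags, mirroring
visual-inspection exclusion. Regressions are reported both with and
without the flagged samples.

On homogeneous synthetic cohorts the naive scale and the regression
slope recover the generative `fcmScale/icmScale` within sampling error
and $R^2 \to 1$ as the population CV shrinks. Under heterogeneous
per-sample intensity scaling (jitter plus gross outliers) a single
linear model leaves structured residuals: Shapiro–Wilk rejects
normality in the large majority of seeded replicates. The package
treats this negative result as a first-class, testable property — it
is the regime in which cross-instrument calibration from such cohorts
is not achievable with one linear transfer function.

## The synthetic-data generator

Real paired FCM/ICM ploidy cohorts are not redistributable, so the
generator emulates the study conditions with known ground truth. Each
cell receives an exact true DNA content — 2N mean $\mu$, 4N mean
exactly $2\mu$, debris uniform on $(0, 0.7\mu)$ — and the same cell is
observed through both instruments with independent multiplicative
Gaussian noise of coefficient of variation `cv` (truncated at zero):
$\mathrm{FCM} = \texttt{fcmScale}\cdot t\cdot(1+\mathrm{cv}\,z)$,
$\mathrm{ICM} = \texttt{icmScale}\cdot t\cdot(1+\mathrm{cv}\,z')$. The
1:2 relation between population means is therefore exact in the
generative model and invariant to both global scales. Default
`cv = 0.03`–`0.05` produces histograms with tight, clearly separated
peaks of the kind healthy blood yields; no published per-population
CVs exist for such cohorts, so this is a realism judgement, fixed once.

Per-object area and granularity are drawn with population-dependent
means (4N granularity 1.5× that of 2N — texture is weakly informative
about ploidy, sufficient for clustering without asserting unmeasured
biology; 4N area only 6% above 2N, keeping area/DNA cross-correlation
low, consistent with the near-independence the PCA stage verifies).
The per-operator granularity columns model instrument faithfulness:
DMG and Prewitt track the signal with ~12–13% noise, Roberts with 20%,
the Sobel column is heavily degraded (80% noise) and the Canny column
carries no population signal at all — giving the operator-selection
stage a realistic discrimination task. These noise levels were set so
that per-sample cluster structure is detectable but not trivially
tight, matching the noisy character of real image-derived granularity.

Cohorts replicate a base specification with optional per-sample
`icmScale` jitter and designated low-intensity outliers
(`icmScale × outlierScale`, `outlierScale < 1`), while `fcmScale` is
held fixed — flow cytometry is the unaltered reference. All
randomness flows from one seed per sample, derived deterministically
from the cohort seed; regeneration is bit-identical.

The image renderer places disk-shaped nuclei (radius 14–20 px,
sinusoidal internal texture, 4N amplitude 1.5× 2N) on a background
with optional linear gradient and additive Gaussian noise, quantized
to a 16-bit raster. Ground-truth IOD is recorded as the exact sum of
painted above-background increments after quantization, so on
noise-free flat-background scenes `extractFeatures` must reproduce it
exactly — the strongest end-to-end oracle in the test suite. Object
placement uses bounded rejection sampling on the center-to-center
separation and fails with the violated constraint named.

What the generator does **not** emulate: optics (no PSF, no
defocus), S-phase cells between the peaks, doublets/aggregates,
dye-bleaching kinetics, and non-disk nucleus shapes. Passing tests
therefore demonstrate correctness of the measurement and calibration
chain under the stated statistical model, not robustness to these
real-data complications.

## Problem sizes and numerical choices

The validation suite runs at deliberately modest scales chosen to make
the statistical assertions sharp but cheap: 17-sample cohorts of 2000
cells for pipeline-level checks (the cohort mean of fitted-peak ratios
then estimates 2.0 to well within ±0.05), 400–600 cells per sample for
replicate-heavy properties (20 seeds for the ratio-SD comparison, 10
replicates for the residual-normality property), 100 random ≤64×64
scenes for exact oracle equivalence of the pixel measurements, and
B = 50 reference sets for gap-statistic checks. Integer-valued test
rasters make sums exact in double arithmetic, so oracle comparisons
can demand bit-identical results rather than tolerances.

Degenerate inputs are handled explicitly: identical points yield
best-k 1 with a warning; a zero-variance feature triggers a
rank-deficiency warning in the PCA; an all-equal histogram collapses
to its single value; zero-distance points get crisp memberships; an
empty annulus falls back to the global background with a logged
status; Gaussian-fit non-convergence falls back to a trimmed mean and
is flagged.

## Limitations

Segmentation quality is assumed: masks are inputs, and mask errors
propagate directly into area and IOD. The calibration stage fits
linear transfer functions only, by design — the peak anchors are
linearly related and a nonlinear map could silently absorb genuine
inter-instrument differences. The residual non-normality finding under
intensity heterogeneity means cohort-level calibration should not be
trusted until per-sample intensity variation (exposure, bleaching) is
controlled upstream; the package flags, but cannot correct, bleached
samples.
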