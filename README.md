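# coneMosaic

Cone photoreceptor mosaic density, repeatability and interocular agreement.

## What this package is for

Adaptive-optics scanning light ophthalmoscopy (AOSLO) resolves single
photoreceptors in the living eye; in cone-dominant animals such as the
13-lined ground squirrel, the split-detection channel shows each cone inner
segment as a paired bright/dark lobe. Cone density (cells/degree²) measured
from such images is the standard metric for tracking the mosaic, but it is
only as useful as its measurement properties: how repeatable one observer
is, how far observers disagree, and whether fellow eyes agree well enough to
use one eye as a control.

`coneMosaic` is for imaging groups who need that validation chain as tested,
reusable code:

* **density** — Voronoi tessellation of cell coordinates; density is the
  number of *bound* cells (finite polygons fully inside the ROI) divided by
  their summed area, which removes edge bias;
* **detection + correction** — an automated split-detection cell finder
  (spectral spacing estimate, dipole-matched difference-of-Gaussians
  band-pass, min-distance regional maxima, amplitude gate, sub-pixel
  refinement) and replay of observer add/remove/shift corrections;
* **repeatability** — within-subject SD `Sw`, repeatability coefficient
  `RC = 2.77·Sw`, measurement error `1.96·Sw`, percent-of-mean, and the
  one-way random-effects ICC with F-based CIs;
* **reliability** — Shapiro-Wilk normality gate, tie-corrected Friedman
  test, Dunn's pairwise comparisons with Bonferroni adjustment, SD-vs-mean
  regression, two-way ANOVA with Sidak-adjusted group contrasts;
* **interocular symmetry** — Bland-Altman bias and 95% limits of agreement
  in difference and ratio (log) form, with proportional-bias testing;
* **image quality** — normalized-variance focus score, power log-log slope,
  intensity SD and MAD;
* **synthetic mosaics** — jittered triangular lattices with known density,
  rendered as split-detection-like images across a quality range, plus
  hierarchical observer measurement tables and fellow-eye pairs, so every
  stage above is testable against ground truth without any imaging data.

## Worked example

Simulate a visual-streak ROI, measure it end to end, then run the
agreement statistics on a full synthetic observer study:

```r
library(coneMosaic)

spec   <- MosaicSpec(eccentricityDeg = 11, seed = 1)  # streak density from the built-in profile
mosaic <- generatePointPattern(spec)
img    <- renderSplitDetection(mosaic, RenderSpec(), seed = 1, imageId = "streak11")
img
#> ROIImage 'streak11': 110 x 110 px, 200 px/deg, 8-bit, eccentricity +11.0 deg, 248 ground-truth cells

sPx   <- latticeSpacing(trueDensity(mosaic)) * 200
cells <- detectCells(img, detectionParams(spacingPx = sPx))
corr  <- simulateObserverCorrections(mosaic, cells, ObserverModel(seed = 2))
res   <- voronoiDensity(applyCorrections(cells, corr, sPx), 0.55, 200)
#> density 795.4 cells/deg^2 from 187 bound cells (truth 820.0)

tab <- simulateMeasurementTable(MeasurementTableSpec(seed = 1))  # 214 x 5 x 3
observerRepeatability(tab)[, c("observer_id", "sw", "rc", "me", "percent_of_mean", "icc")]
#>   observer_id    sw     rc     me percent_of_mean    icc
#> 1        obs1 3.536  9.795  6.931           1.814 0.9997
#> 2        obs2 5.161 14.295 10.115           2.662 0.9993
#> 3        obs3 4.948 13.705  9.697           2.520 0.9994
#> 4        obs4 9.309 25.786 18.246           4.847 0.9977
#> 5        obs5 3.938 10.908  7.718           2.046 0.9996

ba <- blandAltmanRatio(simulateEyePairs(EyePairSpec(seed = 1)))
#> interocular ratio bias 1.008, 95% LoA 0.905 to 1.119
```

Reading the numbers: at the streak the detector finds most cells, the
simulated observer's corrections restore the rest, and bound-Voronoi density
lands within ~3% of the generating truth. In the observer study, each RC
says how far apart two measurements by that observer can be for 95% of
pairs (e.g. observer 1: under ~9.8 cells/degree², about 1.8% of their mean);
the ICCs near 1 say almost all variance is real between-image differences.
The interocular ratio limits say fellow eyes agree within about 10-12% for
95% of locations.

`runPipeline(config, outDir, seed)` chains
simulate → render → detect → correct → density → statistics and writes
per-stage CSVs plus a deterministic JSON summary.

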