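Package: coneMosaic
Title: Cone Photoreceptor Mosaic Density, Repeatability and Interocular
    Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification of cone photoreceptor mosaics from split-detection
    adaptive-optics scanning light ophthalmoscope (AOSLO) regions of interest,
    and the agreement statistics used to validate such measurements. Provides
    bound-Voronoi cone density estimation, an automated cell detector with
    observer-correction bookkeeping, intraobserver repeatability (within-subject
    SD, repeatability coefficient, measurement error, one-way ICC),
    interobserver reliability (Shapiro-Wilk gate, tie-corrected Friedman test
    with Dunn's multiple comparisons), interocular Bland-Altman agreement in
    difference and ratio form with proportional-bias testing, and image-quality
    metrics (normalized-variance focus score, power log-log slope, intensity SD
    and MAD). A synthetic-mosaic generator renders split-detection-like images
    from jittered triangular lattices with known ground truth and simulates
    hierarchical observer measurement noise, so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    deldir,
    EBImage,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
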