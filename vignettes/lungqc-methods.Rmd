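---
title: "Quantifying lung-CT image quality from line density profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lung-CT image quality from line density profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungqc)
```

## The problem

Lung CT offers large dose-reduction headroom because the air–tissue contrast
is enormous, but "how low can the dose go" needs an image-quality metric that
still behaves sensibly under modern denoising reconstructions. Noise-based
metrics (SNR, CNR) are distorted by such reconstructions: they can report
beautifully low noise on an image whose anatomical edges have been smoothed
away. `lungqc` implements a sharpness-based alternative: the steepness of the
HU transition across lung-to-pleura interfaces, measured on line density
profiles, plus the supporting dose and reader-study machinery needed to turn
that number into a "lowest diagnostic dose" statement.

## The sharpness model

A measurement line crosses a tissue interface. Along the Bresenham raster of
the line we record pairs $(l_n, h_n)$ — the Euclidean distance (mm) of pixel
$n$ from the line start and its HU value — and fit the four-parameter
logistic

$$\hat h(l) = \theta_{begin} +
  \frac{\theta_{end} - \theta_{begin}}{1 + e^{-\theta_1 (l - \theta_0)}}.$$

$\theta_{begin}, \theta_{end}$ are the asymptotic HU levels on either side of
the interface, $\theta_0$ locates the transition and $\theta_1$ scales its
slope. The sharpness metric is the magnitude of the derivative at the
inflection point,

$$S = \left| \frac{\theta_1 (\theta_{end} - \theta_{begin})}{4} \right|
  \quad [\mathrm{HU/mm}],$$

with the absolute value because $\theta_1$ is negative on falling profiles.
Note the model is invariant under
$(\theta_1, \theta_{begin}, \theta_{end}) \to
(-\theta_1, \theta_{end}, \theta_{begin})$, so the raw sign of $\theta_1$
carries no information — only $S$ and the transition direction
$\mathrm{sign}(\theta_1(\theta_{end}-\theta_{begin}))$ do.

A scan is summarized by the *pooled median* of a grid of such measurements —
by default 39 interfaces (13 per anatomical level, split 7 left / 6 right,
labelled anterior/lateral/posterior) times 12 replicate line placements
offset 1–6 px along the interface tangent, i.e. 468 measurements. The
replicate factorization (39 × 12) is a design choice: only the two totals,
39 interfaces and 468 measurements, are fixed by the protocol this package
models; the grid config makes the split user-controllable.

```{r example}
spec <- phantom_spec(seed = 1)
slice <- generate_phantom_slice(spec, grid = default_profile_grid(spec))
scan <- measure_scan(slice$image, default_profile_grid(spec))
scan
slice$truth$median_steepness  # ground truth from the noiseless image
```

## Numerical choices in the fit

* **Optimizer.** Bounded quasi-Newton (`L-BFGS-B`) on the sum of squared
  residuals with an analytic gradient. Bounds keep estimates physical:
  $|\theta_1| \le 100\,\mathrm{mm^{-1}}$ and asymptotes in
  $[-1100, 3100]$ HU. Both are configurable.
* **Initialization.** $\theta_{begin}/\theta_{end}$ from the first/last three
  samples, $\theta_0$ at the sample nearest their midpoint,
  $\theta_1 = \pm 4 / \mathrm{span}$. Robust for rising and falling edges.
* **Failure policy.** Optimizer failure or non-finite estimates set
  `converged = FALSE`; `measure_scan()` excludes such fits — and fits with
  estimated contrast $|\theta_{end}-\theta_{begin}| < 50$ HU, which would
  otherwise contribute arbitrary steepness from near-flat profiles — from
  the median, and reports counts and reasons. Exclusion thresholds are
  configurable; errors are reserved for malformed inputs.
* **Sampling limits.** A logistic transition of steepness $S$ with contrast
  $\Delta$ has width $\sim 4/\theta_1 = \Delta/S$. Profiles must sample that
  width with several points: at the common 0.7 mm pixel spacing, edges
  steeper than ~1200 HU/mm (for $\Delta = 840$ HU) collapse to
  sub-pixel steps and the fitted $\theta_1$ sits on a flat likelihood ridge.
  The steep-edge tests therefore use 0.35 mm pixels (a 512 matrix on an
  18 cm paediatric FOV) and, for noisy recovery, edges placed at varied
  sub-pixel positions — which is also what real interfaces do. With the edge
  exactly on a sample point, the noisy median for a 2500 HU/mm edge skews
  high by tens of percent; across sub-pixel placements the pooled median is
  accurate to ~1 %.

## ROI metrics and their conventions

SNR and CNR come from circular ROIs (trachea, liver, air), each enclosing at
least 5000 pixels (a pixel belongs to the ROI iff its centre is strictly
inside the circle; population SD — at these counts the sample/population
distinction is negligible):

$$\mathrm{SNR} = \frac{|\overline{HU}_{tissue}|}{SD_{air}}, \qquad
  \mathrm{CNR} = \frac{|\tfrac12(\overline{HU}_{liver} +
  \overline{HU}_{trachea}) - \overline{HU}_{air}|}{SD_{air}},$$

where $\overline{HU}_{tissue}$ is the mean of the liver and trachea ROI
means. The compound-mean reading of "mean tissue" is ambiguous in the
protocol this models (liver only, trachea only, and the average all fit the
notation); the average is used and isolated in `scan_noise_metrics()`, so an
alternative is a one-line change. Ratios are reported as magnitudes since
air means are deeply negative. Repeated ROI placements are combined by
averaging means and SDs (`average_repeats()`).

## Dosimetry

`compute_mas()`, `compute_dlp()` and `effective_diameter()` are the standard
arithmetic ($mAs = mA \times s$; $DLP = CTDI_{vol} \times$ scan length;
effective diameter $= \sqrt{AP \times ML}$, rounded half-up to whole cm —
the geometric-mean definition from the AAPM size-correction framework).
SSDE and effective dose multiply $CTDI_{vol}$ and DLP by size-dependent
factors looked up (with linear interpolation, and refusal to extrapolate) in
a user-supplied CSV table. The packaged table
(`conversion_factors_synthetic.csv`) is **synthetic**: smooth exponential
curves anchored to published (dose, estimate) value pairs, adequate for
round-trip tests — substitute the published AAPM/Romanyukha tables for real
dosimetry.

## Reader study aggregation

Readers score an overall quality item plus five specific items
(streak artefacts, noise, pleura sharpness, structure sharpness,
small-structure visibility) on 1–4 Likert scales. A scan is *diagnostic*
iff the across-reader mean of the five-item sum strictly exceeds 14 **and**
every reader's overall score is at least 3. The across-reader-mean reading
of the sum threshold (rather than per-reader) follows the protocol's
"average sum" phrasing; both thresholds are arguments. Inter-rater
reliability is ICC(3,k) — two-way mixed, consistency, average measures,
$(MS_R - MS_E)/MS_R$ — with the conventional interpretation bands
(<0.5 poor, 0.5–0.75 moderate, 0.75–0.9 good, >0.9 excellent) and an
F-based confidence interval. Consistency means reader-specific additive
shifts do not change the value; the tests assert exactly that.
`threshold_analysis()` then selects, among diagnostic scans, the one with
minimal effective dose (ties: minimal CTDIvol, then mAs — ties never occur
in practice but the rule is fixed for determinism) and reports its median
steepness as the sharpness cut-off for adequate quality.

Dose–response curves (steepness or SNR against CTDIvol or SSDE) are fitted
by ordinary least squares with degree-2 or degree-3 polynomials; the
confidence band is for plotting, with no inferential claim attached.

## What the synthetic phantom does and does not emulate

The generator renders an axial chest slice — air background (−1000 HU),
soft-tissue body ellipse (+40), two lung ellipses (−800), trachea (−1000),
liver (+60), later compartments winning where shapes overlap — blurs it, and
adds Gaussian noise. Three choices define the stated world:

* **Noise level.** $SD = SD_{ref}\sqrt{mAs_{ref}/mAs}$, the photon-statistics
  law. $SD_{ref} = 27$ HU at 14 mAs is the air-ROI SD implied by the
  reference dose series' SNR at its highest dose level (tissue mean
  −470 HU); it reproduces realistic SNR ranges (~8–17 across 2.8–14 mAs).
  Optional per-kVp multipliers fold beam-quality effects into the same knob.
* **Edge blur.** A fixed detector/optics term (0.6 px) plus a
  *dose-dependent reconstruction term* (0.43 px at 14 mAs, growing as
  $\sqrt{mAs_{ref}/mAs}$). The reconstruction term is essential, not
  cosmetic: with constant blur, additive noise *raises* the fitted median
  steepness at low dose (noise spikes masquerade as steep transitions — in
  simulation the median rises from 420 to >5000 HU/mm as noise SD goes from
  10 to 400 HU), which would make sharpness *improve* as dose falls — the
  opposite of what denoising reconstructions do on real scanners, where
  aggressive low-dose smoothing blurs edges. The dose-dependent blur encodes
  that denoising–sharpness trade-off.
* **Ground truth.** Per-edge true steepness is obtained by fitting the
  noiseless blurred image along the same grid — exact under any compartment
  geometry, where a closed form (e.g. the erf-edge maximum slope
  $\Delta/(\sigma\sqrt{2\pi})$, which is close to but not equal to the
  best-fit logistic steepness) would quietly disagree with the estimand.

What it does **not** emulate: projection-domain physics, beam hardening,
streak artefacts, reconstruction kernels, any actual deep-learning
reconstruction, or real anthropomorphic-phantom HU textures. A green test on
this generator establishes that the measurement pipeline is correct and that
its dose response has the qualitative published shape (monotone rise with
diminishing increments); it does not establish agreement with any particular
scanner's absolute numbers.

One statistical caveat is handled explicitly in the acceptance suite: at
high dose the model's successive median-steepness increments differ by only
~7 HU/mm, below the Monte-Carlo error of a pooled 468-measurement median at
practical test sizes. Concavity is therefore asserted on the generator's
noiseless ground-truth curve (exactly), while the noisy measured medians are
required to rise strictly and to track that curve within 5 %. The SNR curve's
concavity margin is larger and is asserted directly on measurements.

## Interchange formats

Images travel as a headerless CSV pixel matrix plus a JSON sidecar with
pixel spacing and acquisition metadata (`write_ct_image()` /
`read_ct_image()`). DICOM and NIfTI readers are deliberately not bundled —
no suitable reader is available in this package's dependency footprint —
so conversion from scanner formats happens upstream. Grids, ROIs, scan
settings, ratings and conversion tables are all plain CSV with documented
columns.

## Known limitations

* Measurement lines are placed by configuration, not detected; automatic
  interface finding is future work.
* The sharpness metric assumes a single monotone transition per profile;
  profiles crossing two interfaces (e.g. lung–wall–air) violate the model
  and should be excluded by grid design.
* Sub-pixel edges (steepness $\gg \Delta/\mathrm{spacing}$) are not
  estimable from a single profile; the pooled median over sub-pixel-diverse
  placements is the supported estimator in that regime.
* The synthetic conversion-factor table is for testing, not clinical use.
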