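---
title: "Methods: chromatin particle-tracking microrheology with chromotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin particle-tracking microrheology with chromotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the motion model, the measurement chain and its assumptions, the parameters
that matter, what the synthetic generator does and does not emulate, and
the design choices that were genuinely open.

## The measurement

Chromatin mobility is read out from planar trajectories of fluorescent
chromatin-bound probes, summarized as the time-and-ensemble-averaged mean
squared displacement

$$\mathrm{MSD}(\tau) = \left\langle (x_{t+\tau}-x_t)^2 +
(y_{t+\tau}-y_t)^2 \right\rangle,$$

with lag times $\tau$ at multiples of the frame interval $\Delta t$. The
angle brackets are resolved in three stages, in this order:

1. **time average within a track** over all overlapping ordered pairs
   $(t, t+\tau)$ (`track_msd()`);
2. **average over tracks within a cell** — bulk probes (nucleolar,
   telomeric) contribute several tracks per cell, single-locus probes
   exactly one (`ensemble_msd()`);
3. **average over cells**, with the per-lag SEM computed across cells, so
   the reported $n$ is the number of cells.

Cell-first averaging keeps cells — the biological replicates — equally
weighted regardless of how many bulk spots each contains; whether to average
within cells before pooling is genuinely underdetermined by the convention
"$n$ = cells", and the package fixes it this way and documents it.

Before ensemble averaging, tracks whose MSD at the final reported lag lies
more than 3 sample standard deviations from the across-track mean at that
lag are excluded (`remove_outliers()`). The rule is applied in a single
pass with the candidate included in the mean/SD; it is therefore
order-invariant, and deliberately not iterated. It is also sample-size
sensitive by construction: a 100-fold outlier among 21 tracks is removed,
but the same outlier among 10 tracks is not, because one extreme value
inflates a small-sample SD enough to shield itself. The tests pin both
behaviours.

Lags are reported up to 1/3 of the track length (`max_lag_fraction`): the
number of distinct displacement pairs falls linearly with lag, and beyond
about a third of the track the time-averaged estimator becomes so variable
that including it mostly adds noise to fits and comparisons.

Condition comparisons use a two-sample, two-sided, pooled-variance
(classical Student) $t$-test at each lag separately (`compare_msd()`),
with no correction across lags by default; a Bonferroni option exists but
is off, matching common practice in this literature where per-lag
significance is reported descriptively. Lags are strongly correlated, so
the per-lag p-values are not independent evidence.

Anomalous diffusion is summarized by least squares on the log-log curve,
$\log \mathrm{MSD} = \log(4D) + \alpha \log \tau$ (`fit_power_law()`):
$\alpha$ is the anomalous exponent ($\alpha < 1$ subdiffusive, 1 Brownian,
2 ballistic) and $D$ the generalized diffusion coefficient in
µm²/min$^\alpha$.

Directionality is assessed from turning angles — the signed angle between
successive displacement vectors (`directionality()`) — pooled per
condition and tested against circular uniformity with the Rayleigh test
(mean resultant length $R$, finite-$n$ corrected p-value). Interpretation
matters here: *oriented* transport concentrates turning angles near 0,
while subdiffusive chromatin and localization noise both produce a
*reversal* bias (angles near ±180°). A significant Rayleigh statistic at a
mean angle near ±180° is antipersistence, not directed motion, and the
analysis scripts report it as such. Zero-length displacements have no
defined angle; they are skipped and counted.

## Rigid-body nuclear registration

Whole-nucleus translation and rotation would otherwise masquerade as
chromatin motion, so each frame of the nucleus-counterstain channel is
registered onto frame 1 (`estimate_transforms()`):

- **Centre and initial drift.** The rotation centre is the reference
  frame's intensity centroid. The initial drift estimate is the
  frame-to-reference centroid displacement — when the centroid itself is
  the assumed centre, this absorbs exactly the apparent translation that a
  rotation about any other point induces, so the subsequent angular
  estimate sees a pure rotation.
- **Translation.** Fourier cross-correlation with a Gaussian spectral
  weight of SD 2 px (equivalent to circularly pre-smoothing both frames,
  which suppresses the noise-dominated high frequencies of smooth nuclear
  images; a whitened/phase-only variant was measurably noisier on this
  content), with the peak refined on a 1/20-px grid by local
  matrix-multiply DFT upsampling. Integer circular shifts are recovered
  exactly.
- **Rotation.** Both images are resampled on a polar grid about the
  centre (radial step 1.5 px, 720 angular samples, i.e. 0.5°), rows are
  mean-centred, and the angular cross-correlation (per radius, via FFT,
  summed over radii) is maximized with parabolic sub-sample refinement.
  Content whose angular profile is essentially flat (anisotropy below 2%
  of the radial profile variation — e.g. a perfect disk) makes rotation
  undefined; the estimator warns and returns 0.
- **Joint refinement.** Three iterations of: pull the frame back with the
  current estimate, measure the residual rotation, then the residual
  translation, and compose. Composition is exact rigid-transform algebra
  (`compose_increments()`/`per_frame_motion()`), not addition of
  parameters.

A reference of frame 1 (rather than a running reference) avoids error
accumulation across frames. Quantitative tracks use **coordinate-level
correction** (`transform_tracks()`, the exact inverse transform applied to
detected positions) rather than image resampling, which would add
interpolation noise; image-space alignment (`align_stack()`, bilinear) is
provided for visualization and for detectors that require registered
frames, and the test suite checks that the two routes give ensemble MSDs
within 5% of each other.

Assumptions: nuclear motion is rigid in-plane (no deformation, no 3-D
tilt), and the counterstain channel is well exposed. The generator's
default counterstain level (2000 counts against 100-count read noise,
SNR ≈ 20) reflects the latter: a nuclear counterstain is a bright,
extended signal, and with it the per-frame registration residuals are a
few hundredths of a pixel and about a tenth of a degree; a counterstain
at spot-level SNR would make rotation estimates noise-limited.

## Spot detection with noise calibration

Per frame and channel (`calibrate_noise()` + `detect_particles()`):

1. **Background calibration.** Robust statistics (median, MAD-based SD)
   over background pixels. The default background mask excludes pixels
   above the whole-frame median + 3 MAD; a bimodal (Otsu-style) split is
   deliberately not used because on frames whose foreground occupies a
   negligible area it bisects the noise distribution itself and
   underestimates the background SD. A user ROI can be supplied instead.
2. **Band-pass matched filter.** Difference of Gaussians with
   $\sigma_{low} = \sigma_{PSF}$ and $\sigma_{high} = 3\sigma_{PSF}$,
   applied to the background-subtracted frame.
3. **Thresholding in amplitude units.** Local maxima of the filtered image
   are converted to spot-amplitude estimates through the filter's peak
   gain (computed numerically from the discrete kernels) and kept when the
   amplitude exceeds `threshold_k` (default 4) calibrated background SDs.
   The reported `snr` is exactly this amplitude-to-noise ratio, so
   `snr >= threshold_k` holds for every detection, and the detection count
   is invariant under constant intensity offsets. Expressed in
   filtered-noise units the default threshold sits near 9 SDs of the
   filtered background (the filter's white-noise SD gain is likewise
   computed from the kernels), which is what keeps false positives on
   blank frames far below one per frame.
4. **Merging and localization.** Maxima within one PSF radius merge to the
   brighter (ties broken by position order — deterministic). Sub-pixel
   positions come from an iterative Gaussian-weighted centroid (mask SD =
   $\sigma_{PSF}$, window radius $\lceil 3\sigma_{PSF}\rceil$, 3
   iterations, mask recentred each pass): for a Gaussian spot the fixed
   point of this iteration is the true centre, and the matched mask
   suppresses the noise contribution of window pixels far from the spot
   that makes a plain boxcar centroid needlessly noisy.

For single-locus probes, where exactly one spot per nucleus is expected by
construction, `detect_brightest()` bypasses the threshold and returns the
strongest in-nucleus filter response, guaranteeing one candidate per cell.

## Linking and the persistence filter

Frame-to-frame correspondence (`link_frames()`) is greedy
ascending-distance one-to-one assignment, gated at `max_link_distance`
(default 5 px — at minutes-scale intervals chromatin loci move a small
fraction of the typical spot spacing). Ties break by track then detection
index, so the result is independent of detection listing order. There is no
gap closing, merging or motion-model prediction: a missed detection ends a
candidate. This is deliberate — the downstream **persistence filter**
(`filter_persistent()`) keeps only tracks present in every frame of the
movie, so gap-closing heuristics would only manufacture tracks that the
filter exists to exclude. Greedy assignment coincides with optimal
bipartite matching whenever particles are separated by more than twice the
maximum per-frame step, which is the regime the linking tests certify
(exact ground-truth correspondence); the assignment routine is isolated so
an optimal matcher could be swapped in.

Each movie contains one nucleus, so tracks inherit the movie's cell
identity; `validate_against_truth()` additionally checks containment
against the nucleus geometry. Fields of view with several nuclei would
need a mask-based assignment step, which is out of scope.

## The synthetic generator

The generator is the package's ground-truth instrument. Per cell it
simulates:

- **Motion**: fractional Brownian motion per locus — increments are
  fractional Gaussian noise with Hurst $H = \alpha/2$, independent per
  axis, scaled so the 2-D MSD is exactly $4 D \tau^\alpha$. Sampling uses
  circulant embedding (exact spectral synthesis; the suite verifies the
  increment autocovariance against the closed form at 10,000 tracks),
  with an exact Cholesky fallback should the embedding fail. Loci reflect
  at the nucleus ellipse boundary rather than being absorbed, keeping
  every track full-duration as the persistence filter assumes; with
  default mobilities the boundary is rarely touched.
- **Scene**: one elliptical nucleus (default semi-axes 45 × 32 px at
  0.1 µm/px), one condition-labelled locus track plus 1–5 bulk-probe
  tracks started well inside the ellipse, rigid drift and rotation
  composed per frame (defaults 0.3, −0.2 px and 0.4°/frame; arbitrary
  per-frame sequences are supported for registration stress tests).
- **Rendering**: spots as isotropic Gaussians (PSF SD 1.3 px, amplitude
  1000 counts) on a 100-count background; the counterstain channel as a
  smooth ellipse (2000 counts) with ~10 rigidly co-moving chromatin
  texture blobs that give the rotation estimator its angular signal;
  Gaussian read noise (SD = amplitude/10, so spot SNR 10 by default) with
  optional Poisson shot noise. Everything is bit-reproducible under a
  seed.

The five condition presets encode the qualitative biology as simulator
inputs, not claims: bulk and active chromatin share $\alpha = 0.8$,
$D = 2.5\times10^{-3}$ µm²/min$^\alpha$; the repressed locus has
$D = 1.0\times10^{-3}$; the damaged repressed locus is restored to the
bulk preset; and the late-time damaged active locus has
$D = 4\times10^{-3}$ with per-track $D$ drawn lognormally at CV 0.6 —
the lognormal choice (its parameters are otherwise unconstrained) produces
the heavy-tailed, skewed long-lag behaviour seen in late-time damage
measurements. The frame interval defaults to 3 min; 0.1 µm/px and 40
frames are realistic conventions for this kind of acquisition.

What the generator does **not** emulate — and hence what passing recovery
tests do not establish about real data: 3-D motion and defocus, uneven
illumination and photobleaching, nuclear deformation, locus blinking,
cell-to-cell variation in nuclear geometry and expression level, and any
repair biology behind the damage conditions. The recovery results certify
the *measurement chain*, not the biology.

## Numerical choices and degenerate inputs

- Blank (zero-variance) frames are a registration error; constant images
  are a calibration error (`zero spread`).
- Rotation of rotationally symmetric content returns 0 with a warning.
- Zero-variance equal groups in the $t$-test report $t = 0$, $p = 1$,
  flagged `degenerate`; zero-variance unequal groups report $p = 0$ with
  infinite $t$.
- The outlier rule removes nothing when the across-track SD is 0.
- Power-law fits require at least 3 strictly positive MSD values.
- An empty persistent-track set is flagged (`empty = TRUE`, with a
  warning); the pipeline aborts with a stage-named diagnostic rather than
  propagating empty ensembles.
- Seeds: the pipeline derives per-condition and per-cell sub-seeds from
  the master seed, so runs are reproducible end to end and individual
  cells are independently re-simulable.

## Problem sizes

The bundled study (analysis scripts, acceptance script, and the end-to-end
tests) uses 5 conditions × 10 cells × 30 frames at 128 × 128 px — about
three minutes on one CPU — and the statistical checks use up to 10,000
simulated tracks. At 10 cells × 30 frames the sampling SD of the fitted
$\alpha$ for single-locus conditions is ≈ 0.07–0.08 (near the information
limit for ten 30-frame fBM tracks), so a ±0.1 recovery band is a ~1.3 SD
criterion: comfortable in expectation but not guaranteed for every seed.
Larger designs (e.g. 50 cells × 40 frames) shrink this SD to ≈ 0.03 and
the d recovery spread to ≈ 5%.

## Known limitations

Strictly 2-D; rigid-body registration only; no gap closing (by design, see
above); pooled-variance $t$ assumes equal group variances (a Welch variant
would be a one-line change but is not what this analysis tradition
reports); the Rayleigh test addresses first-order orientation only, not
higher-order anisotropy; and MSDs are not converted to viscoelastic moduli
— the generalized Stokes–Einstein step of microrheology is out of scope.
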