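# chromotrack

Particle-tracking microrheology of chromatin loci in live-cell nuclei.

Chromatin is a dense, entangled polymer whose local mobility reports on its
condensation state: transcriptionally repressed, condensed regions move less
than active or bulk chromatin, and DNA damage can remobilize them. The
standard readout is single-particle tracking of fluorescently tagged
chromatin-bound probes — either a single tagged array locus per cell (one
track per cell, so *n* counts cells) or multi-spot bulk probes such as
nucleolar or telomeric markers — imaged as multi-channel 2-D time-lapse
movies at minutes-scale frame intervals.

The measured quantity is the time-and-ensemble-averaged mean squared
displacement at lag time τ (a multiple of the frame interval Δt):

    MSD(τ) = ⟨ (x_{t+τ} − x_t)² + (y_{t+τ} − y_t)² ⟩

averaged over all position pairs within a track, then over tracks within a
cell, then over cells; error bars are the SEM across cells. Anomalous
diffusion is summarized by the power law MSD(τ) = 4 D τ^α (α < 1:
subdiffusion). Before any of this is meaningful, rigid-body nuclear motion
(stage drift, nuclear translation and rotation) must be estimated and
removed so that only intranuclear motion remains.

The package implements the full measurement chain, plus a seeded synthetic
generator so every stage is verifiable by parameter recovery:

| stage | functions |
|---|---|
| synthetic nucleus time-lapses (fractional Brownian loci, rigid nuclear motion, Gaussian-PSF rendering) | `nucleus_scene()`, `simulate_fbm_track()`, `apply_rigid_motion()`, `render_frames()`, `generate_condition_dataset()` |
| rigid registration (translation + rotation) | `estimate_translation()`, `estimate_rotation()`, `estimate_transforms()`, `align_stack()`, `transform_tracks()` |
| calibrated sub-pixel spot detection | `calibrate_noise()`, `detect_particles()`, `detect_brightest()` |
| persistent-track linking | `link_frames()`, `filter_persistent()`, `build_track_set()` |
| MSD statistics | `track_msd()`, `remove_outliers()`, `ensemble_msd()`, `compare_msd()`, `fit_power_law()`, `directionality()` |
| orchestration | `pipeline_config()`, `run_pipeline()`, `validate_against_truth()` |

## Worked example

Simulate and analyse a two-condition study (bulk chromatin vs a repressed
locus), end to end through rendering, registration, detection, linking and
MSD statistics:

```r
library(chromotrack)
cfg <- pipeline_config(conditions = c("bulk", "repressed"),
                       n_cells = 10, n_frames = 30, seed = 42)
res <- run_pipeline(cfg)
res$analyses$repressed$fit$alpha_hat
res$comparisons$repressed_vs_bulk
```

The five-condition study (`analysis/01_simulate.R` …
`analysis/05_validate_recovery.R`, ~3 min total) prints, at seed 42:

```
           condition alpha_hat   d_hat r_squared n_cells
                bulk     0.776 0.00249    0.9974      10
              active     0.756 0.00291    0.9958      10
           repressed     0.719 0.00117    0.9954      10
   damaged-repressed     0.779 0.00273    0.9991      10
 damaged-active-late     0.819 0.00381    0.9989      10

  active_vs_bulk                     significant at 0/9 lags (min p = 0.16)
  repressed_vs_bulk                  significant at 9/9 lags (min p = 5e-10)
  damaged-repressed_vs_bulk          significant at 0/9 lags (min p = 0.25)
  damaged-active-late_vs_bulk        significant at 6/9 lags (min p = 0.031)
```

Read: the generator's presets (α = 0.8 everywhere; D = 2.5×10⁻³ µm²/min^α
for bulk/active, 1.0×10⁻³ for the repressed locus, restored to bulk after
damage, 4.0×10⁻³ with heavy per-cell variability at late times after damage)
are recovered through the full imaging pipeline within ±0.1 in α and ±20%
in D, and the per-lag Student's t comparisons reproduce the expected
pattern: the repressed locus is significantly less mobile than bulk at every
lag, while the damaged repressed locus is statistically indistinguishable
from bulk. Turning-angle analysis (`analysis/04_directionality.R`) finds no
oriented movement in any condition — significant non-uniformity appears
only as a reversal bias near 180°, the signature of subdiffusive
antipersistence, not of directed transport.

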