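---
title: "Methods: daily 3 m LAI from two-sensor fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: daily 3 m LAI from two-sensor fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(laifusion)
```

## The retrieval problem

Leaf area index (LAI, one-sided green leaf area per unit ground area,
m²/m²) is the workhorse structural variable of crop monitoring, but no
single satellite stream offers it at both field-management resolution and
daily cadence. `laifusion` implements a hybrid retrieval that combines two
harmonized surface-reflectance streams:

* a **coarse sensor** (Sentinel-2-like): nine bands at 30 m including
  red-edge (704, 740, 783 nm) and SWIR (1614, 2202 nm), revisiting
  irregularly;
* a **fine sensor** (harmonized CubeSat-like): four bands (490, 560, 665,
  865 nm) at 3 m, daily and gap-free.

The coarse sensor's spectral richness anchors the LAI magnitude (the "gold
reference"); the fine sensor supplies the spatial detail and the daily
cadence. Radiometric harmonization, cloud masking and gap-filling are
assumed to have happened upstream; the package consumes analysis-ready
reflectance and, for testing, simulates it.

## Pipeline

1. **Radiative-transfer training** (`build_training_set`). Canopy, leaf,
   soil and geometry parameters are drawn from wide uniform priors
   (LAI ~ U(0, 7) with 15% of draws enriched in U(0, 0.5) for bare soil;
   chlorophyll 20–80 µg/cm²; leaf water 0.005–0.03 cm; average leaf angle
   30–70°; soil brightness 0–1; solar zenith 20–50°). A forward canopy
   reflectance model maps each draw to the nine coarse-sensor bands, and
   all 19 vegetation indices (Table below) become the predictors for the
   drawn LAI. Gaussian noise (σ = 0.01 reflectance units, the same level
   the scene simulator applies) is added to the simulated reflectance
   before index computation, so the regressor learns the noise-blurred
   mapping it will actually face — without it the forests sit on a
   noise-free manifold and amplify sensor noise through ratio indices.

2. **Coarse LAI ensemble** (`train_lai_ensemble`). Three random forests
   (200 trees, minimum node size 5, √p features per split) are trained on
   the same synthetic set but with different spectral feature sets —
   VNIR+RE (15 indices), VNIR+SWIR (11), VNIR+RE+SWIR (19) — and their
   per-pixel mean (clipped to [0, 8]) is the 30 m LAI; the member spread
   (max − min) is an uncertainty proxy. Combining feature sets regularizes
   the ill-posed inversion: no single band family dominates, and residual
   index-specific noise partially averages out.

3. **Reference sampling** (`build_reference_tile`). The coarse sensor does
   not see every day, and a maize canopy can change quickly, so coarse LAI
   scenes are carried across their acquisition gap multiplicatively:
   a least-squares regression of coarse LAI on the seven shared indices
   (fine-sensor VIs block-averaged to 30 m, pooled over all day-coincident
   pairs) yields a predictor L̂; the change factor for carrying a scene
   from date *s* to target date *t* is L̂(t)/max(L̂(s), ε) with ε = 0.1 LAI,
   confined to [1/5, 5]. Candidates from all scenes within ±24 days are
   weighted by exp(−|gap|/τ) with τ = 10 days, screened against the
   weighted median ± 2 scaled MADs (MAD floored at 0.1 LAI so consensus
   sets keep a usable band; the nearest-date candidate is never screened),
   and averaged.

4. **Downscaling** (`train_rule_model`, `predict`). A rule-based model
   tree links the seven shared indices to the reference LAI at 30 m, then
   predicts at 3 m. The tree uses variance-reduction splits over a
   32-point quantile grid per predictor, minimum leaf 50, maximum depth 6,
   half-open conditions (`< t` left, `>= t` right), a linear model per
   leaf, and bottom-up pruning that keeps a subtree only when it beats the
   node's own linear model after a light complexity adjustment. Leaves are
   linearized into ordered rules; a global linear model guarantees
   coverage. Leaf models are fitted by OLS (QR); a ridge penalty
   (λ = 10⁻³) engages only when a leaf design is rank-deficient or
   ill-conditioned — a fixed ridge would bias exactly linear relationships
   that the tree should reproduce to machine precision. Models are trained
   independently per day and tile ("highly localized"), predictions are
   clipped to [0, 8], and training strictly uses the 30 m grid while
   prediction strictly uses 3 m.

5. **Evaluation and phenology** (`pair_observations`, `lai_metrics`,
   `stage_stats`, `detect_phenology_features`). Plot observations are
   compared against the mean of the 7×7 fine-pixel window (21 × 21 m)
   around each plot center. Conventions, pinned for testability:
   rRMSE = 100·RMSE/mean(observed) in percent; R² from the OLS regression
   of retrieved on observed (an identity-residual variant is available);
   box statistics use type-7 (linear interpolation) quantiles with
   whiskers at Q1 − 1.5 IQR and Q3 + 1.5 IQR; phenology features operate
   on a 7-day centered moving mean — the peak is its maximum, the plateau
   the maximal interval within 5% of the peak lasting ≥ 7 days, senescence
   onset the first post-plateau date opening five consecutive declining
   days, and the green-zero date the first day below 0.2 LAI.

## Vegetation indices

Nineteen indices span the visible (V), red-edge (RE), NIR and SWIR
domains; seven (SR, NDVI, OSAVI, GSR, GNDVI, MTVI2, EVI2) are computable
from the fine sensor's four bands and drive the change model and the
downscaler, while all nineteen feed the coarse-sensor forests. Formulas
are evaluated on band-center reflectances looked up by label, never by
band position. Two are worth flagging:

* **MTVI2** is implemented with the denominator
  √((2·b₈₆₅+1)² − (b₈₆₅ − 5·√b₈₆₅) − 0.5), which differs from the more
  common literature form; `mtvi2_variant = "literature"` switches to the
  published alternative. The default's root argument is provably positive
  over the valid reflectance domain.
* **PSRI** is (b₆₆₅ − b₅₆₀)/b₇₀₄.

Zero denominators yield `NA` with a warning rather than an error, and
`NA` propagates through stacks.

## The forward model

The packaged forward model (`toy_forward`) is a transparent two-stream
caricature: per band, `R = S·exp(−k·LAI) + C·(1 − exp(−k·LAI))` between a
soil spectrum `S` (scaled by the soil-brightness parameter) and an
asymptotic dense-canopy spectrum `C` (visible bands scaled by leaf
chlorophyll, SWIR by leaf water and dry matter, NIR by mesophyll
structure), with extinction `k` per band scaled by the average leaf angle
and a small multiplicative geometry factor. It preserves exactly the
features the retrieval exploits — per-band strict monotonicity in LAI,
NIR saturation (negative second difference), soil/pigment confounding —
while remaining dependency-free and fast enough to render full scenes. A
full PROSPECT+SAIL backend can be plugged into `build_training_set` and
`render_scene` behind the same contract (parameter data frame in, 9-band
reflectance out, deterministic). Band values are taken at nominal center
wavelengths; no spectral response convolution is applied.

## The scene simulator

`generate_truth` emulates the study layout: a 600 × 600 pixel scene at
3 m holding two irrigated fields (peak LAI mean 5.5, planted four days
apart) and one rain-fed field (peak 4.2, planted one day later, earlier
senescence), over a mid-April-to-October season. Per-pixel peak LAI is
the field mean times a smooth correlated heterogeneity field (correlation
length 60 m, amplitude 10–14%) times Gaussian-profile "underperforming
patch" depressions; each pixel follows a double-logistic growth curve
re-zeroed at planting. The coarse sensor acquires every 5 days with 30%
random dropouts; the fine stream is daily and gap-free. Rendered scenes
add Gaussian noise (σ = 0.01) and, for the fine sensor, a per-band
residual harmonization bias (≤ 0.005). Six 20 × 20 m intensive
measurement zones (IMZs) per field are sampled destructively 13/13/11
times with 8% lognormal CV — 222 observations, matching the field-design
arithmetic. Coarse and fine grids are required to nest exactly (one 30 m
cell = a 10 × 10 block of 3 m cells), which the simulator guarantees;
scene-level canopy parameters other than LAI are fixed per date with a
small seeded jitter so the inverse problem stays well-posed at desk
scale.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: atmospheric and BRDF residuals with spatial
structure, cloud-mask leakage, misregistration between sensors,
crop-variety and row-orientation effects, weeds and senescent-leaf
reflectance, and any real PROSAIL-vs-world mismatch. The synthetic
campaign shares its forward-model family between rendering and training,
so absolute accuracies on it are upper bounds, not forecasts, for real
imagery; the study-scale accuracy statements for real fields are
published values, not desk-reproducible ones.

## Numerical choices and degenerate inputs

* Grids are north-up, cell-center registered; map origin is the outer
  corner of pixel (1, 1); coordinate→pixel mapping uses
  `floor((coord − origin)/res)`, so boundary points deterministically
  belong to the next cell.
* Block means and window means skip `NA`; an all-`NA` block or window is
  `NA`. Trailing partial blocks are dropped with a message.
* GeoTIFF output is uncompressed float32 with the geotransform
  (ModelPixelScale/ModelTiepoint), a GDAL-style nodata tag (−9999) and a
  JSON band-label/date/kind record in ImageDescription; round trips are
  bit-exact at float32 precision.
* A rank-deficient change-model pool falls back to a flagged ridge fit; a
  constant-predictor downscaler design collapses to a flagged global
  linear model; a candidate set whose screen would empty always retains
  the nearest-date candidate.
* All randomness is seeded; per-day seeds are derived from the base seed
  and the calendar date (kept within 32-bit range), so any single day can
  be reproduced without replaying the season.

## Problem sizes

The package's own test and demonstration scale, chosen as the smallest
configuration at which the 30 m sampling statistics are meaningful: a
600 × 600 pixel scene (3600 30-m cells, mirroring the one-sample-per-30-m
cell training budget that yields 640,000 samples on a full 8000 × 8000
tile), 50,000 forward runs for the forest ensemble, and a 30-day
greenup-to-peak production window (14 June–13 July) for end-to-end runs —
the window with the fastest LAI change, which is the hardest regime for
the change correction and spans the transition into saturation.

## Known limitations

* Above LAI ≈ 5, reflectance saturates and retrievals are biased low; the
  ensemble clip at 8 bounds but does not remove this.
* The change model is linear in the seven shared indices; abrupt
  management events (harvest, hail) inside an acquisition gap violate its
  smooth-growth assumption and will be smeared until the next coarse
  scene.
* One tile, one projected CRS, no reprojection or mosaicking; grids must
  nest exactly.
* The M5-style tree is a reimplementation of the "rules with linear
  models" idea, not a bit-compatible clone of any proprietary rule-tree
  package; its fit-quality contract (per-day training R² ≥ 0.95 on the
  synthetic campaign) is enforced by the test suite rather than by
  algorithmic identity.
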