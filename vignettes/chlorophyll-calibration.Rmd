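---
title: "Calibrating multispectral leaf sensors against extracted chlorophyll"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating multispectral leaf sensors against extracted chlorophyll}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Hand-held multispectral sensors with six to eighteen wide (20--40 nm FWHM)
channels cost two orders of magnitude less than laboratory
spectroradiometers or SPAD-type chlorophyll meters. To be useful for
nutrient management they must be calibrated species by species against a
destructive reference: leaf disks extracted in dimethylformamide (DMF) and
measured by UV--Vis spectrophotometry. `chlorocal` implements that
calibration pipeline end to end -- spectral normalization, reference
chemistry, outlier screening, model fitting and honest validation -- plus a
simulator of leaf populations so every stage can be exercised and tested
without field data.

Three sensor layouts are supported (`sensor_layouts()`): `vis6` (450--650
nm), `nir6` (610--860 nm) and `full18` (410--940 nm). The 18-channel device
is physically three 6-channel chips with separate apertures; the chip
membership of each channel is recorded in the layout and is configurable,
because published board descriptions disagree with vendor-style groupings.
Analyses that depend on it should report the map used (`chip_map()`).

# From raw counts to a modeling dataset

A reading is normalized channel-wise against a white-reference reading from
the same session, `R = measured / reference`, with `A = -log10(R)`
available as an alternative model input. Reference chlorophyll per disk
comes from the DMF extract equation

```
chl (ug/mL) = 0.18 * (20.27 * A647 + 7.04 * A664)
```

where the leading factor absorbs the cuvette path length and extract
dilution (which is why it multiplies both terms -- the printed form of this
equation is ambiguous and this is the only dimensionally coherent reading),
and is converted to an areal basis by `concentration x volume / disk area`.
The default assay geometry (`reference_assay()`) is three 6 mm punches
(0.28 cm^2 each) pooled in 5 mL of solvent per measurement.

Two outlier screens are applied before modeling:

* **Reference disks.** A disk is excluded when its residual from its leaf's
  mean exceeds three times the pooled within-leaf SD of its species.
  Exclusion peels iteratively -- at most the worst disk per leaf per round,
  with means and the pooled SD recomputed from the survivors -- because a
  single gross disk inflates its siblings' residuals and a one-shot rule
  would discard the whole triplicate. The pooled SD is floored at 1e-6
  ug/cm^2 so a zero-variance species still yields a usable threshold.
* **Spectra.** Mahalanobis distances (`D^2 = (x - mu)' Sigma^{-1}
  (x - mu)`, sample covariance with the n-1 denominator) are computed per
  (sensor x species) dataset and flagged above `mean(D) + 3 SD(D)`.
  Distances over the *full spectra* flag genuinely unusual leaves --
  including perfectly valid extreme ones such as young leaves, which have
  high visible and depressed NIR reflectance. Distances over *replicate
  residues* (one replicate minus the mean of the other two) isolate
  replicate-level measurement error and spare such leaves; residue mode is
  therefore the cleaning default. When the covariance is ill-conditioned
  (condition number above 1e12, common for correlated NIR bands on small
  subsets) a ridge of `1e-8 * trace/p` is added before inversion.

Leaves that lose all replicates are dropped with a warning; surviving
replicates of a partially flagged leaf are kept.

# Calibration model and its selection

The calibration is single-response partial least squares (PLS1, NIPALS),
with mean-centered predictors (reflectances share units, so variance
scaling is off by default but available). The sole hyperparameter is the
number of latent variables (LVs) `k`. Because PLS components nest, a fitted
model retains the whole coefficient path for `1..k`, which the
cross-validation scans exploit.

`k` is chosen by the Akaike Information Criterion,

```
AIC = n * ln(RSS / n) + 2k
```

computed on *leaf-level* predictions: each leaf's prediction is the mean of
its surviving replicates' predictions, and `n` counts evaluated leaves.
Leaf-level scoring matches how the device is used (one decision per leaf)
and how results are reported; spectra-level scoring can be reproduced by
evaluating the model directly. Negative predictions are reported unclipped
so MAE and R^2 stay unbiased.

Model selection and evaluation are separated by a double-nested,
group-stratified Monte-Carlo cross-validation (`nested_cv()`):

* Every split moves whole leaves, never individual replicates, so
  replicate correlation cannot leak across sets.
* Leaves are binned into 10 chlorophyll quantile bins (computed once per
  dataset from leaf-mean reference values, so bin identity is stable across
  repetitions) and every split samples bins equally, with any remainder
  spread over a seeded random bin order; per-bin held-out counts differ by
  at most one.
* Each of 50 outer repetitions holds out 20 of 100 leaves for validation;
  the inner loop repeats a 60/20 train/test split 20 times per candidate
  `k`, fits the path on the training spectra, and scores leaf-level AIC on
  the inner-test leaves. The `k` minimizing mean AIC (ties toward fewer
  components) is refit on all 80 training leaves and scored once on the
  validation leaves. At the defaults the inner loop therefore runs 1000
  splits per candidate `k`.
* The default scan range is 1--6 for 6-channel layouts and 1--16 for the
  18-channel layout. All sizes scale proportionally for datasets that do
  not have 100 leaves.

Randomness flows from one master seed through a documented Lehmer-style
spawning rule (`spawn_seed()`), so the full run is bit-reproducible and any
single repetition can be reproduced in isolation.

`learning_curve()` estimates how many calibration leaves are needed: per
repetition one stratified test set is held out and shared across all
training-set sizes (isolating the size effect), and stratified samples of
each size train a fixed-`k` model. Near convergence the train/test gap
shrinks below sampling noise, so strict train-below-test ordering is only a
reliable expectation while the model is data-limited; the tests assert it
there and on noise-dominated linear data.

`compare_chips()` addresses the 18-channel device's three-aperture
geometry: each chip's six channels are fit with a fixed 5-LV model (the
typical optimum of the 6-channel devices) and compared with the combined
18-channel design over shared stratified splits. The combined design's `k`
is chosen by an AIC scan *inside each split's training pool* -- selecting
it on the full dataset would leak the split's test leaves into the choice
and systematically flatter the combined design.

# What the simulator emulates

`simulate_population()` generates, per species profile
(`default_profiles()`): uniform true chlorophyll over the species' range; a
Beer--Lambert-style mean reflectance `R(lambda) = R0(lambda) *
exp(-k(lambda) * chl)` whose absorption coefficient peaks in the blue and
red and vanishes past the red edge, giving the canonical leaf signature
(low red/blue, moderate green, high NIR plateau) and a monotone,
saturating chlorophyll response; triplicate reference disks whose noisy
per-disk values are converted to exact (A647, A664) pairs, so the extract
equation inverts them by construction; and three replicate raw readings per
leaf per layout, built as reflectance times a fixed white-LED-plus-IR
reference intensity curve with shot-like count noise.

Replicates differ by per-channel relative noise, a per-leaf multiplicative
texture factor, and -- for narrow leaves (rice, sugarcane) -- a convex
mixture with a flat 4% black background whose coefficient is drawn per
replicate (leaf placement). For the three-aperture 18-channel layout that
coefficient acquires a 15% per-chip deviation and each chip additionally
sees its own smooth multiplicative spot-texture perturbation (two Gaussian
log-scale basis curves at 520 and 800 nm, SD `chip_artifact_sd`), emulating
apertures that view different areas of a non-uniform target. A scalar
per-chip factor was rejected during design: independent scalar noise per
chip is simply averaged away by a model that sees all 18 channels, which
would make the combined design always win and could never reproduce the
empirical observation that a single mid-range chip can match or beat the
combined output on narrow leaves.

Species contrasts follow the study's qualitative descriptions: mango and
banana are smooth and quiet (1% replicate noise, no background mixing);
jasmine has the narrowest chlorophyll range (25--55 ug/cm^2) and the
roughest texture; rice mixes in up to 35% background and carries the
largest per-chip artifact (SD 0.08); sugarcane sits in between. Within-leaf
reference noise defaults to 2.5--3 ug/cm^2 per disk, chosen so the mean
absolute deviation of a disk from its leaf mean is close to 2 ug/cm^2, the
scale reported for replicated extraction measurements. Chlorophyll ranges
(5--90 ug/cm^2 for mango down to jasmine's narrow band) bracket published
seasonal and varietal ranges for these crops.

What the simulator deliberately does *not* reproduce: LED radiometry and
integration-time/current effects, thermal drift, midrib and venation
geometry, and any nonlinearity beyond the Beer--Lambert saturation. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
that its qualitative contrasts (smooth species calibrate better; background
mixing degrades accuracy; full-spectrum screening flags young leaves while
residue screening spares them) emerge from the stated mechanisms -- they do
not certify accuracy numbers on real leaves.

# Numerical choices and degenerate inputs

* Covariance inversion adds the ridge described above only when needed;
  distances are reported as `sqrt(D^2)` clipped at zero against rounding.
* AIC is undefined at RSS = 0; the perfect-fit case raises an explicit
  error rather than returning -Inf.
* PLS deflation stops early if the residual covariance collapses; the
  coefficient path is then padded with the last valid component set, and a
  response uncorrelated with every predictor is an error.
* Ties in the AIC scan resolve to the smallest `k`; ties at quantile-bin
  edges resolve by stable sort order, so both are deterministic.
* The spectra-count SD used for injected outliers is population-wide, and
  injected perturbations flip sign per channel: a coherent one-directional
  shift would inflate the covariance along itself and mask the injection.

# Known limitations

* The chip-subset contrast (a single chip beating the combined 18-channel
  design on non-uniform leaves) is reproduced only marginally: for linear
  calibrations a channel superset can underperform a subset solely through
  finite-sample effects and model-selection instability, so under the
  simulator's artifact mechanisms the sign of the comparison fluctuates
  from seed to seed. The package reports both sides of the comparison and
  leaves the interpretation to the analyst.
* Reference-disk screening assumes triplicate disks; leaves entering with a
  single usable disk pass through unscreened.
* The simulator's species profiles are plausibility-calibrated, not fitted
  to any dataset; absolute R^2/MAE values from simulation should not be
  quoted as expected field performance.

# Problem sizes used by the test suite and acceptance script

Simulated populations use the study-shaped 100 leaves x 3 replicates x 3
sensors per species (4500 readings across five species). Nested
cross-validation runs the full 50 x 20 repetitions in the acceptance
checks and reduced repetition counts in unit tests, chosen as the smallest
sizes at which the assessed properties are stable.
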