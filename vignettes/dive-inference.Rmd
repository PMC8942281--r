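---
title: "Inferring seabird dives from GPS trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring seabird dives from GPS trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(divetrace)
```

## The task

A seabird's foraging trip is a sequence of GPS fixes; a time-depth recorder
(TDR) on the same bird tells us, second by second, whether it was under
water. Defining a *dive* as depth strictly greater than 2 m, every position
of a regularly sampled trip carries a boolean label, and dive inference
becomes a 1-D segmentation problem: map a trajectory to a per-position dive
probability. `divetrace` implements the full benchmark for this problem —
data preparation, three neural architectures, two classical baselines,
metrics, and the three evaluation protocols (within-dataset training,
cross-dataset generalization, fine-tuning) — plus a calibrated simulator so
everything runs without access to field data.

## Preprocessing

Raw GPS streams are split into foraging trips (maximal runs further than
`min_distance` from the colony lasting at least `min_duration`; the
thresholds default to 1,000 m and 600 s, chosen conservatively to exclude
colony loitering, and are configurable because the appropriate values are
colony-specific). Trips are linearly interpolated to the 1-s TDR resolution.
Two annotations matter downstream:

* **observed** — whether a second carries a recorded fix (within ±0.5 s) or
  was interpolated; GPS loggers lose fixes while the bird is submerged, so
  missingness is itself informative;
* **coverage** — per position of a `dt`-resampled trip, the fraction of its
  `dt` one-second slots that were observed. We use the resampling interval
  itself as the averaging window; the antecedent definition ("a fixed
  temporal window") leaves the window open and this is the choice that makes
  coverage line up one-to-one with analysis positions.

Downsampling to the analysis resolutions (5, 15, 30 s) decimates
coordinates (keeping every `dt`-th second, which mimics a lower-rate GPS
rather than smoothing it), ORs the dive labels (a window containing at
least one dive second is a dive), and averages coverage. Train / validation
/ test splits (50/30/20, largest-remainder rounding) are made at the trip
level so no window of a test trip is ever seen in training.

## Input features and windows

The networks see three channels over a window of **20 positions** (not 20
seconds: the window is fixed in positions at every resolution so the input
size is constant — 100 s at 5-s resolution, 600 s at 30 s):

1. step speed (haversine displacement over `dt`, R = 6,371 km), z-scored
   with mean/sd fitted on the training split only and reused unchanged on
   validation and test data (sd floored at 1e-6);
2. turning angle, the signed change of heading wrapped to (-π, π] with left
   turns positive (an about-turn maps to +π), scaled by 1/π;
3. coverage, passed through raw (already in [0, 1]).

The scalings keep the three channels on comparable bounded ranges; whether
the original fully-connected approach standardized its inputs is not
documented, so the choice is recorded in the `norm_stats` object attached
to every trained model. Training windows use stride L/2 = 10 (data
economy); inference always uses stride 1 because per-position probabilities
are defined as the mean over *all* windows containing the position.

## Architectures

All three networks map a 3 × 20 window to 20 probabilities via a final
per-position sigmoid. Exact channel widths are fixed so the parameter
totals land on the published budgets, which makes the budgets testable:

* `FCNET` — flatten(60) → 100 → 500 → 500 → 500 → 20, ReLU between hidden
  layers: 567,620 parameters (the published "500k" is loose; the
  discrepancy suggests the original head may have been a single-output
  window classifier, but we standardize on the per-position head used by
  the convolutional models so all three share one output contract).
* `CNNET` — 1-D convolutions with 'same' zero padding: [3→16, k3] →
  [16→32, k3] → [32→32, k3] → [32→1, k1]: 4,865 parameters ("5k").
* `UNET` — encoder (3→24, 24→24, k3), maxpool 20→10, bottleneck (24→48,
  48→48), transposed-conv upsample 48→24 (k2, stride 2), skip
  concatenation (24+24), decoder (48→24, 24→24), 1×1 head: 20,041
  parameters ("20k"). The skip connection lets the decoder combine
  fine-scale speed dips with the coarser area-restricted-search context.

Forward and backward passes are plain matrix algebra (im2col convolutions),
so every gradient is verifiable against finite differences; the test suite
checks a sample of weights in all three architectures at 1e-4 relative
tolerance. Initialization is seeded uniform fan-in scaling.

## Training

The loss is a weighted binary cross-entropy, `-mean(w·y·log p +
(1-y)·log(1-p))`, with probabilities clipped to [1e-7, 1-1e-7] for
stability. The weight `w` counteracts class imbalance; following the study
conditions it defaults to 30 for booby-like datasets (~1 % dives) and 5 for
cormorant-like ones (~9 %). Optimization is Adam (β₁ = 0.9, β₂ = 0.999,
ε = 1e-8) at a fixed learning rate of 0.001, batch size 64, seeded
shuffling. After each epoch both losses are recorded; training stops once
the validation loss has failed to improve for `patience` epochs (default 1
— "as soon as the validation loss starts increasing") and the best-epoch
weights are restored. Batch size, the 100-epoch cap and best-weight
restoration are our choices (the source is silent); patience is
configurable because a patience of 1 under-trains on small noisy datasets —
the benchmark protocols use patience 5.

Fine-tuning is identical training that starts from a pretrained bundle's
weights (all layers unfrozen) with normalization statistics refitted on the
new training split.

## Baselines

**First-passage time.** FPT(i; r) is the time the trajectory spends inside
the circle of radius r centred on position i (backward plus forward first
exit, with linear interpolation of the exact crossing and truncation at the
trip boundary). The radius is selected from 20 log-spaced candidates
spanning the 1st percentile of step lengths to 100× their 99th percentile,
maximizing the variance of **log** passage times (the convention of the
classical FPT literature; the plain-variance variant is available via
`use_log = FALSE`). Ties go to the smaller radius; if passage times are
constant at every radius the median radius is returned with a warning.
Passage times become probabilities by per-trip min-max normalization
(per-trip because the FPT scale drifts with trip-level behaviour).

**Hidden Markov model.** Steps are gamma, turning angles von Mises, fitted
by Baum–Welch EM with exact weighted M-steps (Newton for the gamma shape;
mean-direction/A⁻¹ inversion refined by Newton for κ), scaled
forward-backward recursions, and 3 states for booby-like or 4 for
cormorant-like data. Initialization seeds state means on a quantile split
of step lengths with seeded jitter across restarts (best of 5 kept);
convergence at Δlog-lik < 1e-6 or 500 iterations. Zero-length steps are
floored at 1e-3 m and their angles treated as missing (density 1). The
dive probability is the posterior of the dive state; which state is "dive"
is chosen supervised (the state whose posterior maximizes training-label
AUC) when labels exist, else the smallest-mean-step state. Both rules are
implemented because the original mapping procedure is not documented;
supervised selection is the default.

## Evaluation

ROC curves are exact (unique thresholds, ties grouped), and AUC is the
composite trapezoidal integral — identical, as the tests verify, to the
tie-corrected Mann–Whitney concordance. The reported cross-entropy metric
is unweighted (the training weight is a fitting device, not part of the
evaluation; a flag restores the weighted variant). F-score uses a 0.5
threshold by default. Spatial evaluation builds weighted Gaussian KDE maps
of dive distribution on a 0.01° grid with a 0.25° bandwidth, in degree
space with no geodesic correction (at the study latitudes the distortion is
a few percent, far below the bandwidth); maps are renormalized to integrate
to one before the mean-squared-error comparison, so map MSE is scale-free
and not comparable in magnitude to published tables whose normalization is
unspecified.

## The simulator

The simulator is the package's stand-in for field data: a four-state
behavioural chain (TRAVEL, SEARCH, DIVE, REST) stepped at 1 s — the TDR
resolution, which makes "true dive per second" well defined. Each state
emits a gamma speed (means 12 / 4 / 1.5 / 0.3 m/s, sd 2.5 / 1.2 / 0.5 /
0.2) and a von Mises turn (κ = 50 / 1.5 / 0.8 / 0.5): travel is fast and
straight, search slow and tortuous, rest nearly stationary. REST speeds are
truncated below 1 m/s so the resting statistic (speed < 1 m/s and not
diving, computed on 1-s displacements) maps directly onto REST occupancy;
all speeds are capped at 29 m/s for physical sanity.

Calibration is by construction, not trial and error: mean sojourn times are
fixed (120 s travel, 60 s search and rest, the species' mean dive duration
for DIVE), and the off-diagonal jump weights are solved — a damped Newton
iteration on the embedded chain — so the chain's stationary occupancy hits
the species' published dive and resting fractions exactly. All off-diagonal
transitions are admissible (plunge dives start from transit or search, bout
dives from the surface, birds may fly off after surfacing); with structural
zeros several species' occupancy targets are provably unreachable. Dive
bouts get a half-sine depth excursion strictly above the 2-m threshold with
a peak sampled from a species range — only the threshold crossing matters
downstream. GPS gaps are deleted in contiguous geometric-length runs
(submersion makes fix loss bursty) until the deleted fraction hits the
species target within half a percentage point, endpoints pinned. Dive bout
durations are geometric with the correct mean; their standard deviation is
not separately matched (the published sds are of the same order as the
means, which geometric dwell approximates).

What the simulator does **not** emulate: environmental forcing, prey
fields, central-place attraction beyond starting at the colony,
device-specific GPS error, or any correlation between gaps and dives (gaps
are placed independently of the behavioural state, although in real
cormorant data they co-occur with submersion). Passing benchmarks on this
synthetic data therefore demonstrates that the pipeline learns the
speed/tortuosity/context signature of diving as modelled — it does not
certify performance on any real colony's data.

## Protocol sizes and numerical choices

The bundled benchmark uses 48 simulated booby-like trips with durations
drawn from the species distribution (~43 h of trajectory), which gives
test-set AUCs stable to a few hundredths across seeds; the fine-tuning
study pretrains on 30 cormorant-like trips and fine-tunes on 5 of 14
masked-booby-like trips at 15-s resolution, replicated over seeds. The
simulator calibration checks integrate 2×10⁷ seconds per species in the
test suite (occupancy autocorrelation from ~60-s sojourns makes shorter
runs noisy at the half-percentage-point tolerance) and 4×10⁶ in the
acceptance script, where the tolerance question is one of reporting rather
than pass/fail. Probability clipping at 1e-7, the gamma-shape Newton
tolerance (1e-10), the EM tolerance (1e-6), the step-length floor (1e-3 m)
and the sd floor (1e-6) are stability guards whose values are far below any
quantity of scientific interest. Maxpool ties keep the first element;
split rounding is largest-remainder; all RNG flows through per-call seeds
so every result in the package is exactly reproducible.

## Known limitations

* The HMM is a faithful re-implementation, not a numerical twin of any
  particular reference package; likelihoods agree with exhaustive
  enumeration on short sequences but fitted optima can differ from other
  software's under different initialization schemes.
* FCNet's parameter total (567,620) exceeds the loosely published "500k";
  the architecture table is fixed and tested rather than reverse-engineered
  further.
* Map MSE magnitudes are defined on normalized densities and are not
  comparable to published MSE tables with unknown normalization.
* Whether overlapping-window probabilities should also be averaged inside
  the training loss is untested; we average at inference only, which is the
  only reading consistent with window-level batching.
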