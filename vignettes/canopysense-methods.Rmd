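---
title: "Methods: from mobile sensor streams to per-tree canopy physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from mobile sensor streams to per-tree canopy physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopysense)
```

canopysense implements the processing chain of a vehicle-mounted urban
tree monitoring rig: an upward RGB camera, a radiometric thermal camera,
a nine-sensor metal-oxide (MOS) gas array with GPS and
temperature/humidity sensing, driven along a street transect past a line
of anchored trees. This vignette explains each model, the assumptions
behind it, the tunable parameters, and the choices made where the
methodology left room.

## Canopy structure from cover photography

Upward photographs through a canopy are strongly bimodal in the blue
channel: sky scatters blue, foliage absorbs it. The analysis chain is

1. blue-channel histogram (`channel_histogram`),
2. threshold at the valley between the two peaks
   (`detect_valley_threshold`), pixels strictly above the threshold being
   sky (`binarize_sky_canopy`),
3. gap analysis on a 5×5 sub-image grid (`grid_gap_counts`): a sub-image
   whose sky proportion is at least 0.75 is a *large gap*, i.e. a
   between-crown opening rather than a within-crown pore,
4. cover metrics (`cover_metrics`).

With total pixels $N$, gap (sky) pixels $G$, and large-gap pixels $G_L$:
foliage cover $f_f = 1 - G/N$, crown cover $f_c = 1 - G_L/N$, crown
porosity $\phi = 1 - f_f/f_c$. Beer–Lambert extinction then gives

$$\mathrm{LAI} = -\,f_c \ln(\phi)/k, \qquad
\Omega(0) = \frac{(1-\phi)\,\ln(1-f_f)}{\ln(\phi)\, f_f}, \qquad
\mathrm{LAIe} = \mathrm{LAI}\cdot\Omega(0),$$

with light-extinction coefficient $k = 0.5$ (spherical leaf-angle
distribution) and $\Omega(0)$ the zenith clumping index correcting for
non-random foliage placement. The printed form of the clumping expression
is ambiguous as typeset in parts of the cover-photography literature; we
use the form above, which is the dimensionally consistent one from the
gap-analysis methodology this chain follows, reduces to
$\Omega(0)\to 1$ as $f_f \to 0$, and keeps LAIe ≤ LAI for clumped
canopies. Likewise the definitions of $f_f$ and $f_c$ as one minus the
total-gap and large-gap fractions are taken from that methodology; the
tallies themselves (large-gap, total gap, total pixels) are the stated
inputs.

Numerical choices:

* **Valley detection.** The field procedure picks the histogram valley by
  hand. We automate it: an 11-bin moving average smooths the counts; the
  two tallest local maxima at least 30 bins apart (and at least 5% of the
  tallest peak, to reject tail noise) are the sky and canopy modes; each
  peak is refined to the raw-count maximum in its window; the threshold
  is the raw-count minimum strictly between the refined peaks, ties going
  to the lowest intensity. A manual threshold can be passed anywhere the
  automatic one is used, preserving the original workflow. A unimodal
  histogram raises an error rather than guessing.
* **Porosity clamping.** $\phi$ is clamped to
  $[10^{-4}, 1-10^{-4}]$: a fully closed crown ($\phi = 0$) would
  otherwise give infinite LAI from a finite photograph.
* **Grid remainders.** Image dimensions not divisible by 5 merge the
  remainder rows/columns into the last grid row/column, so every pixel is
  counted exactly once.
* **Degenerate scenes.** $f_c = 0$ (pure sky) returns all metrics 0;
  $f_f \to 0$ with crowns present collapses LAI to 0 through the clamp.

## Water status from thermal frames

Upward radiometric sky temperatures are tens of degrees below air
temperature while foliage tracks it, so canopy segmentation is a
temperature cutoff (default 0 °C, exposed as `sky_cutoff`); pixels
*above* the cutoff are canopy. The phrase "filtering temperatures lower
than 0 °C" could be read either way; we keep the canopy warm side
because that is the physically meaningful one for upward frames.

Wet and dry reference temperatures — the extremes of a fully transpiring
and a non-transpiring leaf — are taken as the 5th and 95th percentiles of
the in-frame canopy distribution (linear interpolation between order
statistics). Manual referencing (wetting leaves, petroleum jelly) is
impossible from a moving vehicle; the percentile stand-in is declared as
such and the percentiles are parameters (`p_wet`, `p_dry`). One
consequence worth knowing: because the references are drawn from the same
frame as the canopy mean, a frame's raw stress index self-centres near
0.5; contrast between frames comes from the distribution's shape and from
multi-frame aggregation, and absolute calibration would need external
references.

The indices, for canopy temperature $T_c$:

$$\mathrm{raw} = \frac{T_c - T_{wet}}{T_{dry} - T_{wet}}, \qquad
I_g = \frac{T_{dry} - T_c}{T_c - T_{wet}}, \qquad
\mathrm{CTD} = T_c - T_{air}.$$

The raw index is the classic crop water stress index; TWSI is its value
clipped to $[0,1]$ (the raw value is preserved separately). $I_g$, the
infrared stomatal-conductance index, is not printed in the methodology
this implements; the form above is the standard one from the thermal
index literature it builds on, and is capped at `ig_max = 10` as
$T_c \to T_{wet}$ where it diverges. $T_{air}$ comes from the E-nose
ambient temperature channel. Campaign summaries use the $n-1$ standard
deviation (0 for a single frame).

## Geofenced per-tree fusion

Tracks are densified to 10 Hz by per-axis linear interpolation on a
uniform grid containing both endpoints. Around each anchored tree a
circular geofence is built with radius
$\min(\text{15 m}, d_{prev}/2, d_{next}/2)$ — half the ground distance to
each neighbour, capped at 15 m (typical street-tree half-spacing) — which
makes adjacent regions disjoint by construction, so no sample can be
attributed to two trees. Ground distances use the equirectangular
approximation, whose error over sub-10 km transects is millimetres —
negligible against any radius. Entry and exit are the first and last
timestamps of each contiguous in-region run; an out-and-back pass yields
two intervals whose samples are pooled into one per-tree mean. Camera
(30 fps) and E-nose (1 Hz) streams are aggregated independently against
the same intervals — no cross-resampling — and a tree with no samples in
a window gets `NA`, never zero. Multiple frames falling in one tree's
window are averaged, the natural reduction for a per-tree value. Altitude
is carried through but unused by the geometry.

## Feature scaling and the network

The network input is the printed 10-vector — MQ-3, MQ-4, MQ-8, MQ-135,
MQ-136, MQ-137, MQ-138, MG811, temperature, humidity. MQ-7 is deployed on
the array and parsed and summarised everywhere else, but excluded from
the input vector to keep the 10-20-4 architecture meaningful. Scaling to
$[0,1]$: voltages /5 (5 V supply), temperature /50, humidity /100,
LAI /5 (field maxima near 4.8), TWSI and clipped $I_g$ as-is, and CTD
mapped affinely from $[-20, 20]$ °C — the affine min–max map
$(\mathrm{ctd}+20)/40$ being the only $[0,1]$ map consistent with the
stated range and the other rules. Out-of-range values are clipped with a
warning rather than dropped (per-tree means are already aggregates;
whether the original workflow clipped or dropped is unstated, and
clipping keeps trees). Rows with missing parameters are dropped, not
imputed. The split is a seeded uniform permutation labelled 70/15/15
(sizes rounded to the nearest row: $n=101$ gives 71/15/15).

The network is feed-forward with 20 logistic-sigmoid hidden units and a
linear 4-output layer, trained by Levenberg–Marquardt: per epoch, solve
$(J^\top J + \mu I)\,\delta = J^\top e$ over the training rows ($J$ the
analytic Jacobian of the residuals with respect to all 304 weights),
accept only steps that reduce training MSE, dividing $\mu$ by 10 on
success and multiplying on failure within the epoch. Training stops at
the epoch cap, on $\mu$ overflow ($>10^{10}$), or after 6 consecutive
epochs of rising validation MSE — a common early-stopping patience; the
original tool's rule is unstated — returning the best-validation weights.
Initial weights are uniform on $[-0.5, 0.5]$ from a seeded generator (the
original initializer is unstated); fixed seeds make training
bit-reproducible. Evaluation reports MSE over all $n \times 4$ entries
and a *pooled* Pearson R between flattened predictions and targets,
because a single R per stage is the reported convention; per-output R is
also logged. A second untouched dataset can be evaluated as an
"additional test" stage.

## Statistics

PCA is computed on z-scored variables (the fused table mixes volts, °C,
hPa and unitless indices, so the correlation-matrix form is the only
defensible one), components ordered by decreasing eigenvalue, and each
loading column's sign fixed so its largest-magnitude loading is positive
— plot orientation is arbitrary, reproducibility is not. Constant columns
are an error naming the column. The Pearson matrix is pairwise-complete
with two-sided p-values from $t = R\sqrt{(n-2)/(1-R^2)}$; pairs with
fewer than 3 complete observations are `NA`.

## What the synthetic generators emulate — and what they do not

`gen_canopy_scene` builds scenes on the same 5×5 grid the analysis uses:
cells are filled with overlapping elliptical crown blobs (clipped to
their cell) until the large-gap-based crown cover reaches the target,
residual cover is spread over partly-filled edge cells, and circular
holes are punched inside crowns until porosity reaches the target. The
realized $f_f$, $f_c$, $\phi$ are bookkept from the true noiseless mask
*under the gap-analysis definitions*, so "truth" is exactly what the
scene presents to the method. Sky and canopy render far apart in blue
(220 vs 60) with Gaussian colour noise (sd 10), enough to exercise valley
detection without overlapping the modes. Real frames add what these
scenes deliberately omit: exposure variation, clouds, sun glare, mixed
boundary pixels, branches and trunks, and histogram valleys far shallower
than the synthetic ones — so passing recovery tests demonstrates the
correctness of the computation, not field robustness of the thresholding.

`gen_thermal_scene` draws canopy pixels from a Gaussian and sky at a
fixed cold temperature; `gen_transect` lays collinear anchors at fixed
spacing with a constant-speed pass (5.6 m/s, the surveyed transect speed)
and optional GPS jitter; both record exact truth. `gen_linked_dataset`
draws a latent per-tree state (LAI in $[0.3, 4.8]$, stress index in
$[0.45, 0.9]$, spanning the observed field ranges), derives canopy
temperature, $I_g$ and CTD through the same thermal relations the
pipeline uses (references fixed at 15/35 °C), and maps the latent state
through seeded monotone sigmoid response curves into voltages —
positive responses to leaf area and stress, negative for the CO₂ cell —
mirroring the reported field correlation structure, with Gaussian
voltage noise. It is a smooth noiseless-to-mildly-noisy world: the
network recovery it supports shows the trainer and scaler are correct
and that the reported accuracy regime is attainable on data with this
structure, not that field data are this learnable.

## Problem sizes

The test suite and the acceptance script use 400×400-pixel scenes for the
recovery sweep (4 cover × 3 porosity targets × 3 seeds), 50 random masks
up to 200×200 for brute-force gap-count checks, a 20-tree transect at
10 Hz for geofence recovery, $n = 500$ linked trees for the regression
regime check, and 150-pixel frames for the six-tree end-to-end campaign —
sizes at which every recovery quantity is already stable to well inside
its tolerance.

## Known limitations

* The percentile wet/dry referencing self-normalises each frame (see
  above); absolute stress levels require external references.
* Thresholding assumes a bimodal blue histogram; overcast low-contrast
  frames can fail detection and then need the manual threshold.
* Geofences are circles on a locally flat earth; dense urban canyons with
  multipath GPS will blur entry/exit times beyond the 0.1 s recovered on
  clean synthetic tracks.
* The clumping correction is evaluated at the zenith only, as in the
  cover-photography method it follows.
* JPEG frame input is not supported (PNG/TIFF only), keeping image I/O
  lossless.
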