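---
title: "Methods behind twitchkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind twitchkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twitchkit)
```

twitchkit quantifies the function and maturation of optogenetically paced
skeletal myotubes from two kinds of raw data: time-lapse movies of
light-triggered contractions, and multi-channel fluorescence stills
(α-actinin, DAPI, α-bungarotoxin, smFISH probes). This vignette explains
the models and procedures each module implements, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the choices made where the underlying methods left room.

Throughout, image coordinates are 1-based pixel-center coordinates with
the origin at the top-left (`x` = column, rightward; `y` = row, downward).
Displacements stay in px/frame inside the PIV layer; micrometres and
seconds appear only at the trace boundary.

## Displacement fields: multipass FFT cross-correlation PIV

`correlate_pair()` estimates the displacement field between two frames by
windowed cross-correlation, in the configuration standard for myotube
recordings: a 64 px interrogation window in the first pass and 32 px in
the second (`pass_windows = c(64, 32)`), 50% overlap, and window
deformation between passes.

Each window pair is mean-subtracted and correlated by zero-padded FFT. The
correlation plane is divided by the per-lag overlap count — the "unbiased"
cross-correlation estimator. This matters: with plain circular
correlation, the triangular overlap taper skews the peak toward zero in
proportion to the displacement; on the generator's speckle (whose
autocorrelation is several pixels wide) we measured gain errors of 15–20%
that way, versus <0.001 px with the normalized estimator.

The integer peak (searched within `max_displacement`, default a quarter
window) is refined by a 3-point Gaussian fit per axis, falling back to a
parabolic fit when a stencil value is not positive. Identical frames give
exactly zero: the autocorrelation plane is symmetric, so both fits return
zero offset.

Two preprocessing/validation layers bracket the correlation:

* **Image high-pass** (`highpass_sigma`, default 4 px): each frame has a
  Gaussian-blurred copy of itself subtracted before correlation. Smooth
  structures much larger than the speckle — nuclei, ribbon shading —
  otherwise superpose a broad component on the correlation peak; a 3-point
  fit applied to such a two-scale peak mislocates it by up to 0.2 px. The
  high-pass keeps the speckle (grain ~3 px) and removes the rest. This
  mirrors common practice in PIV image preprocessing.
* **Normalized median validation** (threshold 2.0, normalization floor
  0.1 px): each vector is compared per component with the median of its
  valid 8-neighbors; outliers are replaced by the mean of the valid
  neighbors and flagged `replaced`. Windows with no texture (standard
  deviation at numerical zero) are flagged invalid outright.

Between passes the previous field is validated, interpolated bilinearly to
every pixel (clamped beyond the grid hull), and used to deform the second
frame; the next pass measures only the residual. Because the residual is
near zero wherever the predictor is good, any remaining estimator bias is
suppressed by the deformation pass.

`track_point()` integrates the fields Lagrangianly from a reference
position — in this assay, a myonucleus, which is how single-cell
displacement is defined for these cultures. Velocity is the per-interval
step length over the frame interval, i.e., the finite-difference speed of
the tracked point rather than an average of PIV magnitudes over the cell;
displacement is the distance from the starting position. A trajectory that
leaves the grid hull truncates the trace and flags it.

## Twitch kinetics

`detect_extrema()` finds local extrema whose prominence is at least
`prominence_fraction` (default 0.1) of the trace's global range. A
relative threshold is used because traces span cells of very different
amplitudes. Candidates are found on a lightly smoothed copy of the trace
(binomial kernel, `smooth_window = 3`): without it, sampling noise splits
flat twitch summits into double peaks whose dip prominence exceeds any
reasonable threshold. Each retained extremum is then snapped back to the
raw-series extremum within the smoothing window (nearest tie wins), so
clean traces are analyzed exactly as sampled. Alternation is enforced by
keeping the more extreme of same-kind neighbors. Boundary samples may
serve as *leading* minima (recordings start at stimulation onset), but the
final sample never closes a twitch — a relaxation that runs past the end
of the recording would otherwise be scored too short.

`dissect_twitches()` emits one event per minimum–maximum–minimum triple:
amplitude is peak minus preceding minimum, acceleration time spans start
minimum to peak, relaxation time peak to closing minimum.

`dominant_frequency()` takes the largest non-DC amplitude of the FFT of
the mean-subtracted trace, zero-padded fourfold (bin width 0.125 Hz for
the standard 2 s at 20 ms/frame), and returns 0 when no bin exceeds 5×
the median spectral amplitude. The reported `period` is its reciprocal;
where a spatial "wavelength" is quoted for these recordings it is
interpreted as this temporal period, since the trace is a time series and
the quantity is paired with frequency. The single-twitch duration
(acceleration + relaxation) is also available from the event table for
the alternative reading.

`contraction_velocity()` is the mean of the per-interval instantaneous
speeds over the first 2 s (the analysis window used for these cultures);
the mean, not the peak, matches "averaged over 2 s".

`fatigue_time()` defines cessation statistically, since no analytic
criterion exists for "stopped moving": the trace begins with an
unstimulated baseline; fatigue is the first instant after onset from which
the rolling RMS velocity stays below 2× the baseline RMS for at least 1 s.
The rolling window defaults to 1 s: with substantially shorter windows,
single noise spikes keep interrupting the sub-threshold run and push the
detected time late by ~15%; at 1 s the detected time tracks the analytic
envelope-crossing time of decaying synthetic traces to a few percent. A
culture that never moves fatigues at time 0; one that never stops returns
`NA`.

## Morphometry

`preprocess_channel()` follows the standard projection–subtraction–
binarization chain: maximum-intensity z-projection, background subtraction
by grayscale morphological opening with a disc (the top-hat approximation
of rolling-ball subtraction), Otsu thresholding, and removal of components
below `min_area_px` (default 20 px; the nucleus size filter is a choice,
as segmentation pipelines rarely state one).

`width_metrics()` computes the proportional α-actinin area, then divides
the myotube area by the total centerline length to get the average width.
The centerline is a Zhang–Suen thinning skeleton; length sums inter-pixel
steps (1 for 4-neighbor steps, √2 diagonal, diagonals that shortcut an
existing 4-path not double-counted). Endpoint branches shorter than the
local width (2× the distance-map value at their junction) are pruned
first: thinning a rectangle grows X-shaped spurs at the ends which inflate
length and deflate width. On straight ribbons 8–40 px wide the estimator
is within 10% and monotone; the residual bias is the skeleton stopping
half a width short of each tube end.

`assign_myonuclei()` labels DAPI components with 8-connectivity and calls
a nucleus a myonucleus when at least half its area overlaps the actinin
mask (boundary inclusive — "residing within" is operationalized as
`overlap ≥ 0.5`). Density is myonuclei per mm² of image.

`nuclei_spacing()` projects centroids to arc-length positions along the
tube centerline and takes consecutive gaps after sorting; uniformity is
the coefficient of variation of the gaps using the population SD ("SD
divided by mean" with no n−1 statement; the sample-SD alternative is a
one-line change and Euclidean neighbor distances are available via
`method = "euclidean"`). Arc-length projection was chosen because nuclei
in curved tubes are neighbors along the tube, not along the chord.

## AChR and smFISH scoring

`btx_background()` histograms per-nucleus mean BTX intensities into 64
bins over their observed range and returns the center of the most
populated bin (ties to the lower bin). At least 10 nuclei are required —
fewer make the modal bin unstable, and the error message advises pooling
images. `classify_high_btx()` flags nuclei strictly above 2× this
background; a nucleus at exactly twice background is not flagged, making
the boundary deterministic.

`cluster_shape()` uses the standard morphometric definitions: circularity
`4πA/P²` with the perimeter from the 8-connected boundary chain (diagonal
steps √2), roundness `4A/(π·major²)` with the major axis from the
second-moment ellipse (central moments carry the 1/12 per-pixel extent
correction so digitized rectangles reproduce their continuous moments).
Components under 5 px are flagged unreliable rather than rejected.

`perinuclear_region()` returns the tube-mask pixels whose arc-length
projection lies within ±50 µm of the nucleus's projection — the band in
which receptor-subunit and filamin transcripts are counted.
`count_spots()` counts 8-connected FISH components with areas inside
`[min_area_px, max_area_px]`; a spot belongs to the region its centroid
falls in, so boundary straddlers count exactly once. Spot size bounds are
exposed parameters with no universal default. Densities are normalized by
the caller-supplied area: myotube-region area for receptor/filamin
probes, myonucleus area for myosin heavy-chain probes, matching the two
normalizations used for those probe families.

## Statistics

`rout_outliers()` implements ROUT for the location-only (horizontal-line)
model — the form relevant to univariate boxplot data. The robust center
is an iteratively reweighted mean under Lorentzian weights
`1/(1+(r/RSDR)²)`; RSDR is the 68.27th percentile of absolute residuals
with an n/(n−1) correction. Candidates are tested from the most extreme
inward against the step-down FDR ladder `α_i = (Q/100)·i/n` (the i-th most
extreme point is the i-th smallest p, so this is the Benjamini–Hochberg
rung), flagging while `p < α_i`. With Q = 1 a planted 10σ point in n = 50
is flagged essentially always while clean normal samples see a mean
flagged fraction of ~0.02%.

`unpaired_t_test()` is the pooled-variance two-sample t test (Welch via a
flag); zero-variance degenerates resolve deterministically (equal means →
p = 1; unequal → p = 0 with a warning). `pearson_r2()` wraps the
product-moment correlation with the t-transform p-value and Fisher-z 95%
CI. `ddct()` computes per-sample ΔCt against the housekeeping gene,
ΔΔCt as the treated-minus-control group means, fold change `2^−ΔΔCt`, and
calls significance only when |log2FC| strictly exceeds 0.5 — the cutoff
band is read as exclusive on both sides. Outlier removal in the pipelines
is applied per group before testing; this is configurable, as the
alternative (pooled removal) is equally defensible.

## The synthetic-data generator

Every test fixture is generated in code with exact ground truth.

*Traces.* Waveforms are raised-cosine twitch trains: `sine` is
`A/2·(1−cos 2πft)`; `asymmetric_twitch` rises for `acceleration_fraction`
of each period and falls for the rest (both phases raised cosines, so the
signal is smooth); `fatigue_decay` multiplies the sine train by
`exp(−t/decay_time)`. Ground truth lists every complete cycle's extrema
times, amplitude and phase durations. Defaults follow the assay's
acquisition: 2 s at 20 ms/frame, pacing at 2, 5 or 10 Hz.

*Movies.* A base image — background 10, speckled ribbon (uniform noise
smoothed to ~3 px grain, amplitude 40 over a ribbon level of 50),
soft-edged tube mask, nuclei as smooth bright domes with the speckle
suppressed beneath them (as in brightfield, where nuclei appear smooth;
this also makes their photometric centroid well defined) — is low-passed
below Nyquist with a raised-cosine roll-off, emulating the microscope PSF.
Each frame is then the base translated rigidly along the tube axis by the
waveform's instantaneous displacement via the Fourier shift theorem, which
is exact for a band-limited image at any subpixel offset; integer shifts
reproduce the source frame to floating point. Rigid translation (no local
strain) keeps the tracker's ground truth exact; heterogeneous contraction
is deliberately out of scope. Per-frame Gaussian noise is added last.

*Stills.* Channels are rendered as filled geometry: actinin ribbons, DAPI
disks, BTX disks at either the background level or a stated multiple of it
(default 3×), FISH puncta disks — plus Gaussian noise. Nuclei of one tube
closer than the sum of their radii plus 1 µm are rejected so counts stay
unambiguous. Ground truth records widths, nuclei positions and classes,
the high-BTX proportion, puncta coordinates and per-tube spacing
statistics.

*Ct tables.* Control ΔCt is fixed; treated ΔCt is offset by the requested
log2 fold change, so the expected `2^−ΔΔCt` equals `2^log2FC` exactly at
zero noise.

What passing on these fixtures does **not** show: robustness to focus
drift, photobleaching, non-rigid contraction, overlapping nuclei, spot
clusters below the resolution limit, or staining variability — none of
which the generator emulates. The generator validates the measurement
code, not the microscope.

## Problem sizes and numerical choices

Movies are rendered at 128×192 px (0.5 µm/px, 100 frames at 20 ms) — large
enough for the 64 px first pass with margin for ±4 px motion, small enough
that a full movie's field sequence computes in seconds. Width calibration
uses 600 px ribbons so skeleton end effects stay under the 10% band.
Fatigue traces run 15 s with a 2 s baseline at 5 Hz, amplitude 20× the
displacement noise. Statistical calibrations use 10,000 null draws for
p-value uniformity and 100–200 trials for ROUT rates. Ties are broken
deterministically throughout: lower modal bin, strict `>` at the 2× BTX
threshold, centroid membership for boundary spots, nearest tie when
snapping extrema.

## Known limitations

* The PIV engine is 2D, single-camera, and assumes texture; it does not
  do ensemble correlation or GPU batching.
* The width estimator underestimates skeleton length (hence overestimates
  width) near tube ends; errors grow for tubes shorter than ~10× their
  width.
* Spacing and perinuclear measurements need a single dominant tube per
  mask component; dense overlapping cultures require instance
  segmentation, which is out of scope.
* Fatigue detection depends on a recorded pre-stimulation baseline; traces
  without one cannot be scored.
* ROUT here is the location-only model; regression ROUT (outliers from a
  fitted curve) is not implemented.
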