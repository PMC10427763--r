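# twitchkit

Quantitative analysis of optogenetically paced skeletal myotube cultures.

Skeletal muscle cells differentiated in vitro can be made to contract on
demand by expressing channelrhodopsin-2 and pulsing blue light. Chronic
light pacing ("optical training") changes how the cells contract and how
they mature, and both effects are measured from microscopy: contraction
kinetics from high-speed time-lapse movies, and structural/expression
maturation from fixed multi-channel fluorescence images. twitchkit
implements that measurement stack for R users — lab members analyzing
their own recordings, and method developers who need a fully synthetic,
ground-truthed benchmark of the pipeline.

## What it computes

**Contractility** (from movies, 20 ms/frame):

- Displacement fields by multipass FFT cross-correlation PIV
  (interrogation windows 64 → 32 px, 50% overlap, window deformation,
  3-point Gaussian subpixel peak fit, normalized-median vector
  validation).
- Single-cell displacement traces by Lagrangian tracking of a nuclear
  reference point: displacement `d(t) = |x(t) − x(0)|·px` and
  instantaneous velocity per frame interval.
- Twitch kinetics from each trace: events are minimum–peak–minimum
  triples of the prominence-filtered extrema, giving amplitude,
  acceleration time (min → peak) and relaxation time (peak → min);
  dominant frequency from the zero-padded FFT (bin width 0.125 Hz at the
  standard 2 s / 20 ms acquisition); mean contraction speed over 2 s; and
  fatigue time — the first instant after stimulation onset from which the
  rolling RMS velocity stays below 2× the pre-stimulation baseline RMS
  for ≥ 1 s.

**Maturation** (from α-actinin / DAPI / α-bungarotoxin / smFISH stills):

- Average myotube width = α-actinin area / centerline-skeleton length;
  proportional stained area; myonuclei (DAPI components with ≥ 50%
  overlap with the actinin mask) and their density per mm².
- Myonuclei spacing along the tube centerline: mean neighbor gap and its
  coefficient of variation (population SD / mean).
- AChR-positive nuclei: mean BTX intensity per nucleus, background from
  the modal histogram bin, positives strictly above 2× background; AChR
  cluster area, circularity `4πA/P²` and roundness `4A/(π·major²)`.
- smFISH spot counts inside perinuclear bands (tube pixels within ±50 µm
  of the nucleus along the centerline), densities per µm² of myotube
  region or myonucleus area depending on the probe.

**Statistics**: ROUT outlier identification (Q = 1, location-only model),
two-tailed pooled-variance t tests, Pearson r² with Fisher-z CI, and
qPCR fold changes `2^−ΔΔCt` with significance only beyond
|log2FC| > 0.5.

**Synthetic data**: every assay above has a generator with exact ground
truth — contracting speckle-textured movies rendered by Fourier-shift
rigid translation, morphology scenes with planted tubes/nuclei/puncta,
and Ct tables with known fold changes. All fixtures used by the tests are
generated in code; nothing needs downloading.

## Worked example

Render a 2 s movie of a myotube paced at 5 Hz with 2 µm peak
displacement, run the full contractility pipeline, and read off the
kinetics:

```r
library(twitchkit)

scn <- scene_spec(
  image_size = c(128L, 192L), pixel_size = 0.5,
  tubes  = list(list(centerline = cbind(c(16, 80), c(32, 32)), width = 20)),
  nuclei = data.frame(x = 48, y = 32, radius = 4, tube = 1L))

mv  <- generate_movie(
  waveform_spec("sine", frequency = 5, amplitude = 2,
                duration = 2, sample_interval = 0.02),
  scn, seed = 1)

res <- run_contractility(mv$movie, run_config(),
                         point = c(96.5, 64.5), output_dir = NULL)
res$summary
#>   contraction_velocity dominant_frequency period mean_acceleration_time
#> 1                20.47                  5    0.2                    0.1
#>   mean_relaxation_time n_twitches fatigue_time
#> 1                  0.1          9           NA
```

The tracked nucleus moved at 20.5 µm/s on average (the analytic mean
speed of this waveform is `2·A·f` = 20 µm/s), the dominant frequency is
the pacing frequency exactly, and each of the 9 complete twitches splits
into a 0.1 s acceleration and a 0.1 s relaxation phase — the half-period
of a symmetric 5 Hz twitch. Per-event detail comes from
`dissect_twitches(res$trace)`:

```r
head(dissect_twitches(res$trace), 3)
#>   start_min_index peak_index end_min_index peak_time amplitude
#> 1               1          6            11       0.1      2.04
#> 2              11         16            21       0.3      2.04
#> 3              21         26            31       0.5      2.04
#>   acceleration_time relaxation_time
#> 1               0.1             0.1
```

Amplitudes recover the planted 2 µm within ~2%. The morphology pipeline
is symmetric: `generate_morphology_image()` renders the four channels,
`run_morphology()` returns width, density, spacing, AChR and spot tables.

A thin command-line wrapper ships in `inst/cli/twitchkit`
(`twitchkit simulate|piv|kinetics|morpho|spots|stats ...`) for shell use.

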