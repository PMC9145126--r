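# dmoct

Dynamic-contrast microscopic OCT (dmOCT) processing for corneal epithelium,
with a synthetic layered-cornea speckle phantom for end-to-end validation.

## The problem

Microscopic OCT resolves ~1 µm in all three dimensions, but corneal
epithelial cells scatter too uniformly to be distinguished in a single
B-scan. Dynamic-contrast processing recovers cellular contrast from *time*:
a stack of co-registered B-scans (e.g. 150 frames at an effective B-scan
rate of 111 Hz, 1.35 s of recording) is Fourier-transformed per voxel, and
the integral spectral amplitude in three frequency bands is rendered as an
RGB image —

* blue: slow fluctuations, 0–0.5 Hz (essentially static tissue),
* green: medium fluctuations, 0.5–5 Hz,
* red: fast fluctuations, 5–25 Hz,

so color encodes the time scale of sub-resolution intracellular motion.
Healthy basal epithelial cells render yellow (balanced medium/fast power)
under a blue superficial layer. Toxic stress (e.g. the eye-drop preservative
benzalkonium chloride, BAK) changes the picture in a characteristic order:
epithelial swelling and a drop in the **motility coefficient**, then a
**hue red shift** of the basal cells, then delayed stromal swelling.

This package implements the full analysis chain for researchers working with
such stacks — and, because raw animal data are not redistributable, a
dynamic-speckle cornea phantom that emulates the exposure time course, so
every stage is testable against known ground truth.

## What it computes

For a B-scan time series `X(t, z, x)` with `n` frames at rate `f_s`:

* **Temporal spectrum** `A_k(z,x) = |Σ_t X(t,z,x) e^(-2πikt/n)|`,
  one-sided bins `k = 0..⌊n/2⌋` at `k·f_s/n` Hz (no window, DC retained).
* **Band integrals**: per voxel, the sum of `A_k` over bins whose center
  frequency lies in each half-open band; fast→R, medium→G, slow→B (the DC
  bin belongs to the slow band). Channels are min–max normalized to [0,1]
  and optionally histogram-matched to a moving-SD reference image
  (window 25 frames).
* **Motility coefficient**: per-ROI mean of the per-pixel temporal
  CV = SD/mean of amplitude — `sqrt(4/π − 1) ≈ 0.5227` for fully developed
  dynamic Rayleigh speckle.
* **Hue metrics**: RGB→HSV, hue histogram wrapped green-to-green
  ([120°, 480°), so blue = 240°, red = 360°, yellow = 420°), circularly
  smoothed peak detection (1 peak for the basal ROI, 2 for the total
  epithelium).
* **Thickness**: mean columnwise mask extent × axial pitch, in µm.
* **Repeatability**: CV and coefficient of repeatability `1.96·√2·SD`.

## Worked example

Simulate one acquisition of the default phantom after 90 minutes of the
exposure course, process it, and measure:

```r
library(dmoct)
cfg <- make_default_cornea(list(n_ascans = 64, n_depth = 320))
summary(cfg)
#> phantom acquisition: 150 frames @ 111 Hz -> recording time 1.351 s,
#>   fluctuations analyzable up to 55.5 Hz (Nyquist);
#>   64 A-scans (7.812 um/px lateral), 320 depth px (1 um/px axial),
#>   5 repeats per time point

sim <- simulate_series(cfg, exposure_min = 90, course = toxicity_course(),
                       repeat_index = 0)
img <- process_series(sim$series, histmatch = FALSE)

motility_coefficient(sim$series, sim$masks$basal_epithelium)
#> [1] 0.3670856   # down from 0.42 at baseline: motility loss

find_hue_peaks(hue_histogram(img, sim$masks$total_epithelium), n_peaks = 2)
#>   hue_deg   height
#> 1   378.5 305.6667   # basal peak, red-shifted from its 420 deg baseline
#> 2   240.5 184.8889   # superficial layer, still blue

thickness_from_mask(sim$masks$total_epithelium, cfg$axial_um_per_px)
#> [1] 69              # um; swollen from 40 um at baseline

repeatability_stats(c(0.361, 0.355, 0.368, 0.359, 0.364))
#> $cv  [1] 0.01364917
#> $cor [1] 0.01371459
```

At baseline (`exposure_min = 0`) the same pipeline reports a basal peak at
~420° (yellow), a superficial peak at ~240° (blue), basal motility ~0.42 and
40 µm epithelial thickness; the stroma does not swell before 150 minutes.

`run_timecourse(study_config(...), output_dir)` runs the whole in-silico
study (control + exposed groups, exposure grid 0–270 min every 30 min, five
repeats per time point) and writes per-repeat and per-eye CSV metrics tables
plus averaged RGB renderings; `summarize_groups()` collapses the table to
group mean ± SD.

## Command line

```sh
dmoct simulate --config cfg.json --out DIR [--exposure 90] [--seed 1]
dmoct process  --stack stack.tif --out img.png --bands 0:0.5,0.5:5,5:25 --window 25
dmoct metrics  --stack stack.tif --mask basal.png --roi basal --axial-um 1 --out m.csv
dmoct study    --config study.json --out DIR
```

The script installs to `system.file("exec", "dmoct", package = "dmoct")`.
Stacks are multi-page float32 TIFF (plus a JSON sidecar header), masks and
RGB images 8-bit PNG, metrics CSV.

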