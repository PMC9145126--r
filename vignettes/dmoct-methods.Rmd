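---
title: "Dynamic-contrast OCT processing and the cornea phantom: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-contrast OCT processing and the cornea phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The processing model

dmOCT derives contrast from temporal fluctuations of the backscattered
amplitude. The chain implemented here, in order:

1. **Per-voxel temporal spectrum.** Each voxel's `n`-frame amplitude series
   is Fourier transformed with no window function and no detrending; the
   one-sided magnitudes at bins `k = 0..⌊n/2⌋` (center frequencies
   `k·f_s/n`) are kept. With the default 150 frames at 111 Hz the axis
   extends to the Nyquist frequency 55.5 Hz with Δf ≈ 0.74 Hz.
2. **Band integrals.** The *integral amplitude* of a band is the sum of
   spectral magnitudes over the bins whose center frequency lies in the
   band's half-open interval. Defaults: slow [0, 0.5) Hz → blue,
   medium [0.5, 5) Hz → green, fast [5, 25) Hz → red. Bins at or above
   25 Hz are discarded.
3. **Per-channel min–max normalization** to [0, 1] over the whole image.
4. **Histogram matching** of each channel to a moving-SD reference image of
   the same acquisition (window 25 frames), by monotone 256-level CDF
   matching.
5. **Repeat averaging** of the five acquisitions per time point, pixelwise.

Assumptions worth stating: the B-scans are already co-registered (no bulk
motion — valid ex vivo, not in vivo); amplitudes, not complex fields or
log-intensities, are the processed quantity throughout; and the acquisition
is stationary over the 1.35 s recording.

## Numerical and interpretation choices

* **DC belongs to the slow band.** At the default geometry the slow interval
  [0, 0.5) Hz contains only the DC bin, which is why blue renders the static
  tissue. Half-open intervals with bin-center membership make the assignment
  unambiguous (at 150 frames / 111 Hz: slow = {0}, medium = {1..6},
  fast = {7..33}).
* **"Integral amplitude" = sum of magnitudes**, not power. Band
  completeness then holds exactly: the three integrals sum to the total
  spectral amplitude below the fast band's upper edge.
* **Constant channels normalize to 0** — a channel with no dynamics should
  display as dark, not saturate.
* **Moving-SD reference.** Whether the reference is one window or an average
  over all sliding windows is not pinned by the source description; the mean
  over all `n − w + 1` windows is implemented (less noisy, same
  expectation). `window = n` reduces to the global SD image and equals the
  SD projection, which is tested as an internal consistency check.
* **Histogram matching ties** map to the lowest reference quantile attaining
  the source CDF value, so the map is monotone and rank-preserving;
  quantization error is bounded by one 1/255 level.
* **Order of operations** follows the natural reading of the processing
  description: integrals → normalization → histogram matching → averaging.
  The alternative order (matching before normalization) is reachable through
  `process_series()` flags.
* **Metrics vs display.** Quantitative hue metrics are computed on the
  *normalized* image, with histogram matching applied only to rendered
  output. Rationale: matching all three channels to one shared reference
  forces identical channel marginals, which is desirable for display
  contrast but distorts the relative channel magnitudes that the hue metric
  is meant to summarize. This is a design decision on a point the source
  description leaves open.
* **Hue wrapping and peaks.** Hues are wrapped green-to-green
  ([120°, 480°); blue 240°, red 360°, yellow 420°) so the yellow→red shift
  of stressed basal cells is a continuous decrease. Pixels with saturation
  < 0.1 or value < 0.05 are excluded (hue is numerically meaningless
  there; both thresholds configurable). Peak finding smooths the histogram
  circularly (9-bin moving average), collapses plateaus to their central
  bin, suppresses peaks within 30° of a taller one, and breaks height ties
  toward the lower wrapped degree.
* **Motility coefficient** is the per-pixel temporal CV (sample SD / mean of
  amplitude) averaged over the ROI — the "normalized SD" reading; the
  original supplement detailing the exact normalization is not available,
  so this standard definition is adopted and documented. It is
  scale-invariant and equals `sqrt(4/π − 1) ≈ 0.5227` for i.i.d. Rayleigh
  amplitudes, which the phantom reproduces.
* **Thickness** is the mean columnwise mask extent × axial pitch — robust to
  small mask holes, exact on the phantom's rectangular ground-truth masks.

# The phantom: a stated world

The generator emulates the acquisition protocol (150 B-scans of 512 A-scans
over 0.5 mm at 111 Hz; five repeats per time point; exposure sampled every
30 minutes from 0 to 270) on a layered cornea. Amplitude-domain synthesis is
used rather than complex-field simulation: every downstream operation
consumes amplitudes, so Rayleigh-type amplitude statistics and band-limited
temporal fluctuations are sufficient and much cheaper.

Within a layer, each pixel's signal is
`mean_amplitude · texture · (1 + fluctuation)`, where the fluctuation is a
sum of sinusoids at band-interior bin-centered frequencies with per-pixel
random phases — bin-centering avoids spectral leakage, so single-band layers
place their AC amplitude entirely in the matching channel, and leakage
behavior is tested separately with an off-bin tone. A band's variance share
is `fluctuation_strength² · band_power_fraction`; the remainder of the power
budget is static, so the realized temporal CV is
`fluctuation_strength · √(Σ fractions)`. Fully dynamic speckle layers
instead draw i.i.d. Rayleigh amplitudes per frame. Additive Gaussian
detector noise (SD `noise_sigma`, default 0.005) is applied last and the
result clamped at zero.

Baseline layers (1 µm axial pitch): superficial epithelium 15 px, bright and
nearly static (blue); basal epithelium 25 px, dimmer with equal medium and
fast band integrals (`p_med·n_med_bins = p_fast·n_fast_bins`, hence yellow)
and realized CV 0.42, textured into 8 px cells; stroma 84 px, weakly
fluctuating. The 40 µm epithelium and 84 µm stroma match healthy adult
mouse cornea.

**The surface-film anchor.** A thin (3 px) high-motility interface layer
sits above the epithelium, outside every analysis ROI. It exists because
per-channel min–max normalization is scale-free: if one tissue layer
attained the maximum of both the green and red channels, any transfer of its
power between the medium and fast bands would be invisible after
normalization. Real scans contain bright dynamic interface structures
(tear film, debris) that anchor the channel ranges; the phantom needs an
explicit analogue. Its band weights are chosen so its two channel integrals
are equal, keeping it hue-neutral.

**The toxicity course** is phenomenological — the source observations are
time points, not kinetics, so every rate is a parameter:

| parameter | default | meaning |
|---|---|---|
| `epi_swell_max` | 2.0 | epithelial thickness factor at plateau (doubles by the end) |
| `epi_swell_tau_min` | 120 min | saturating-exponential time constant |
| `plateau_min` | 150 min | epithelial thickness exactly constant afterwards |
| `stroma_onset_min` | 150 min | stromal factor is exactly 1 before this |
| `stroma_swell_per_min` | 0.01/min | linear stromal growth after onset (~2.2× at 270 min) |
| `motility_decay_per_min` | 0.0015/min | basal `fluctuation_strength · e^(−rate·t)` |
| `redshift_rate_per_min` | 0.0004/min | basal band-power fraction moved medium→fast per minute |

The swelling factor is normalized so the plateau value is reached *exactly*
at `plateau_min` (and is constant after), the stromal factor is exactly 1
before onset, and the medium→fast transfer conserves total dynamic power, so
the red shift leaves the motility coefficient untouched — the two effects
are independently controllable. Layer extents are rounded to whole pixels
and restacked downward from the fixed top surface. Control eyes are
re-simulated independently at every time point (fresh speckle realizations,
baseline dynamics), emulating repeated imaging sessions.

**Seeding.** One master seed; every (repeat, exposure, eye, group) stream is
derived from it by a small integer hash kept below 2³¹, so repeats are
independent but the whole study is bit-reproducible, byte-identical CSVs
included. The generator saves and restores the global RNG state.

# What a green test does and does not establish

The phantom reproduces: the acquisition geometry and constants; Rayleigh
amplitude statistics; band-limited per-layer fluctuation spectra; the
qualitative exposure ordering (motility drop from the first exposure point,
substantial basal red shift by 90 min, stromal swelling only after 150 min);
and exact mask/geometry ground truth. It does **not** reproduce: real
speckle spatial correlation (pixels are independent); bulk motion; optical
effects (PSF, confocal gating, refraction, attenuation with depth); the
endothelium; absolute motility of the superficial layer (its slow
fluctuations cannot be represented as periodic power inside (0, 0.5) Hz at
Δf = 0.74 Hz, so its simulated CV is lower than measured values — slow-band
power with no available bins is rejected rather than silently folded into
DC); or the source study's measured animal values, which would require its
raw data. Green acceptance tests therefore establish correctness of the
*processing and metrics* against stated ground truth and closed-form
statistics, not biological fidelity of the numbers.

# Known limitations

* The motility normalization and the histogram-matching position in the
  chain follow documented readings of an ambiguous description; both are
  isolated behind flags/arguments so either interpretation is reachable.
* Hue peaks are computed per repeat and then averaged; computing them on the
  five-repeat-averaged image is equally defensible and not implemented as a
  default.
* The TIFF I/O is a minimal uncompressed float32 implementation (no R TIFF
  binding is assumed); it reads only what its writer produces and rejects
  everything else with a format error. One test validates the output against
  an independent Python TIFF reader.
* At very long exposures the combination of motility decay and red shift can
  drive the basal hue past red toward magenta; the defaults are chosen so
  the peak stays in the red range over the 0–270 min grid.
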