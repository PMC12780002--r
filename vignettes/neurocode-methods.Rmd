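---
title: "Methods: MEA signal analysis for tumor-neural interaction studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA signal analysis for tumor-neural interaction studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocode)
```

## Scope and model of the data

`neurocode` analyses multichannel extracellular voltage recorded by a
microelectrode array (MEA) under glioma–neuron co-culture: 32 electrodes at
200 µm pitch, sampled at 30 kHz, with baseline noise of a few µV and two
signal populations — brief biphasic neuronal spikes (duration
1.2 ± 0.3 ms, mean inter-peak interval 8.5 ms) and prolonged multiphasic
tumor potentials (1–15.6 ms, interval CV 32%). The package implements the
full computational chain: denoising and zero-phase filtering, noise-robust
spike detection, unsupervised template-library classification of spike
waveforms into recurring "neural codes", spectral and time–frequency
feature extraction, a recurrent generator of stimulation event sequences,
and population-level quantification of tumor invasion by the Cell
Migration Center (CMC).

No public recordings accompany this problem domain, so the package ships a
first-class simulator (`synth_recording()`, `synth_event_corpus()`,
`synth_migration()`) whose defaults encode the signal statistics above.
Every stage is validated against that ground truth.

## The synthetic recording model — and what it does not capture

`sim_config()` defaults are the study conditions: Gaussian baseline noise
of SD 2.4 µV (≈ ±5 µV range), neuronal firing as a Poisson process with a
2 ms dead time tuned so the realized mean inter-peak interval is 8.5 ms,
tumor events as a gamma renewal process with interval CV 0.32, linear
summation of overlapping spikes, a shared common-mode component (8 µV of
50 Hz mains plus 15 µV of 0.1 Hz drift — deliberately nontrivial so
common-mode removal has a real target), int16 quantization at
0.195 µV/count, and 10% lognormal amplitude jitter. Spike SNR is defined
as peak amplitude over baseline noise SD. An optional cell–electrode
coupling model attenuates inserted amplitudes by the point-contact
equivalent circuit ratio `R_seal / |R_seal + Z_membrane + Z_electrode|`,
evaluated at a 1 kHz reference frequency (mid-band of spike energy; the
choice of reference frequency is ours).

The simulator does *not* emulate electrode drift over hours, bursting or
network-state dynamics, overlapping-unit waveform superposition at one
electrode beyond linear addition, or non-Gaussian electrode noise. Tests
passing on this generator therefore demonstrate algorithmic correctness
under the declared statistics, not performance on every pathology of real
recordings.

Spike templates are built from sign-alternating sine lobes (two lobes for
neuronal, 3–6 for tumor shapes), normalized to unit peak. One construction
detail matters: symmetric lobes can tie two adjacent samples at the peak,
which makes peak alignment ambiguous by one sample; the generator breaks
such ties explicitly so that every template has a strict extremum.

For clustering-recovery experiments, `plant_code_templates()`
rejection-samples templates whose pairwise sample consistency stays below
0.8 — recovery of planted classes is only well-defined when the planted
classes are actually separated under the classification metric.

In `synth_migration()`, a logistic invasion front advances along the
electrode row (fast and saturating by day 4 under the `hyper` profile,
slow under `normal`), and each day's counts follow a discretized Gaussian
around the front. Cells keep one shared uniform draw across days
(common-random-numbers inverse-CDF sampling), so each simulated cell's
position is monotone over days and the population CMC never retreats by
sampling noise alone, while each single day keeps exactly the multinomial
marginal around the front. An independent multinomial per day would
violate front monotonicity at the plateau about half the time — an
artifact of sampling, not biology — which is why the coupled construction
is the default.

## Preprocessing chain

Two documented chains mirror the two roles of filtering
(`preprocess_recording()`):

* **detect**: common-mode removal (subtract the per-sample cross-channel
  mean) → zero-phase Butterworth band-pass 1–3000 Hz, order 2.
* **lfp**: common-mode removal → zero-phase Butterworth low-pass 3 kHz,
  order 2.

Zero-phase means forward–backward application: no group delay, so spike
peak indices survive filtering (verified to within one sample on clean
template insertions). Traces are odd-reflection padded by three times the
low corner's time constant (3·rate/low_hz samples) before `filtfilt`; the
1 Hz corner's transient decays over roughly a second, so in-band amplitude
accuracy (1% on a 100 Hz tone) is a *steady-state* property — traces
shorter than ~3 s of padding room retain small edge transients.

Common-mode removal subtracts the channel mean, which also injects
−1/n of every channel's spikes into all channels. With the 32-electrode
array (or the 8-channel test configurations) that leakage stays well below
threshold; with only 2–3 channels it does not, which is why few-channel
recordings should skip the stage.

Savitzky–Golay smoothing (order 5, frame 501) reproduces degree-≤5
polynomials exactly, but at 30 kHz its 16.7 ms frame attenuates a 1.2 ms
spike ~40-fold: it is a trend/clarity smoother, not part of the detection
chain, and is therefore off by default there.

Wavelet denoising uses an in-package periodized orthogonal Daubechies-4
transform (4 levels) with the universal soft threshold
`σ·sqrt(2 log n)`, σ estimated as MAD/0.6745 of the finest detail level —
Gaussian noise is suppressed (>20% SD reduction; in practice ~75%) while
isolated spikes retain their peak within 15%. The adaptive Kalman stage is
a scalar random-walk filter whose measurement variance adapts to an
exponentially weighted innovation power; it tightens on clean signals and
smooths noisy ones. Which denoisers enter which analysis is a
configuration choice, not hard-wired.

## Threshold refinement and detection

The naive threshold is `AVG + factor · STD` with population (divisor n)
statistics; the refined statistics are recomputed over samples with
`|x| <` that threshold only, giving the modified threshold
`AVG′ + factor · STD′`. One refinement pass is the default; `iterate =
TRUE` repeats until the exclusion set stabilizes. Iteration matters in
dense-firing regimes: at the 8.5 ms mean interval, spikes occupy ~14% of
samples, a contamination level at which a single pass still leaves the
noise SD inflated and the resulting threshold close to the spike peaks
(F1 ≈ 0.91 at SNR 5), while the converged threshold detects reliably
(F1 ≈ 0.99). The one-pass estimate is also noisier on short (< ~10 s)
recordings. The
default factor is 4, the midpoint of the conventional 3–5 range; values
outside that range warn but are allowed. Detection takes local extrema
with `|x| ≥` threshold in both polarities by default, separated by a 2 ms
refractory period (earlier peak wins). Waveforms are extracted in a 4 ms
window (2 ms pre + 2 ms post) and re-centred on the window extremum so the
alignment sample is the waveform peak.

On band-limited Gaussian noise alone, a 4σ two-polarity detector fires at
the level-crossing rate of the band (~1.3 events/s for a 3 kHz band) —
this is physics, not a bug. On realistic noise-only recordings the shared
mains/drift component inflates the threshold estimate on any channel where
it is not cancelled, and the false-positive rate drops to ~0; at the
default firing statistics (117 spikes/s) the crossing rate is negligible
against true events (F1 ≈ 0.99 at SNR 5).

## Neural-code classification

Sample consistency between a peak-aligned waveform and a template is the
fraction of positions whose deviation, *relative to the template peak
magnitude*, is within the 30% tolerance. Normalizing by the peak rather
than per-sample values keeps the metric dimensionless and stable at
zero-crossings (an ε = 1e-9 guard covers degenerate flat templates). A
waveform joins the first template in library order reaching 90%
consistency (`best_match = TRUE` switches to highest-consistency
assignment); otherwise it founds a new code, and the founding waveform
remains the code's template while a min/max envelope tracks the member
range. The library is therefore order-dependent by construction; identical
input order reproduces identical libraries.

One practical consequence of the metric: samples outside a short spike are
near zero in both waveform and template and agree "for free", so the
discriminative fraction shrinks as the window grows. Distinguishing
sub-millisecond shape variants demands windows matched to the template
span.

## Features and discrimination

Waveform properties use documented conventions chosen once: duration is
the span where `|x| ≥ 10%` of peak, rise time 10→90% on the leading edge,
decay 90→10% on the trailing edge (linear sub-sample interpolation),
slope the maximum absolute first difference, interval integral the area
under `|x|` between the duration endpoints, and frequency the snippet's
dominant spectral peak. Band power is a Hann-windowed Welch estimate
integrated over the band (theta 4–8 Hz, gamma 30–100 Hz presets), with
fractions relative to a declared total band. Morlet energies use an
analytic Morlet CWT (ω₀ = 6) over 8 logarithmic bands spanning
0.1–5 kHz, evaluated at three log-spaced frequencies per band.

The Hilbert–Huang stage is an in-package EMD: cubic-spline envelopes
through local extrema (two mirrored extrema per edge), Cauchy sifting
threshold 0.05, 50-sift cap (capped sifts are flagged, not errors).
Completeness is structural: the residual is defined as the input minus the
IMF sum. Per IMF the features are energy, amplitude²-weighted mean
instantaneous frequency (FFT Hilbert transform, 10% edge trim), and sample
entropy (m = 2, r = 0.2·SD, traces decimated above 1000 samples).

Feature selection is recursive elimination under a ridge-regularized
linear discriminant (λ = 1e-3 of the mean covariance diagonal; importance
is the sum of absolute discriminant coefficients) — deterministic, with no
random restarts. The same discriminant is the default classifier in
seeded, stratified k-fold cross-validation; any classifier with the
`(train_x, train_y, test_x)` signature can be plugged in. In the
validation experiments, waveforms are wavelet-denoised before feature
extraction; at SNR 10 the 10%-of-peak duration threshold sits at the raw
noise SD, so properties measured on raw noisy snippets are uninformative
while denoised ones separate neuronal from tumor shapes nearly perfectly.

## The sequence generator

Event sequences are (code type, inter-peak interval) pairs. The model is
a two-layer recurrent network (LSTM by default, GRU selectable) with 128
hidden units per layer, dropout 0.3 between layers, and two output
branches: softmax over code types (categorical cross-entropy) and a
softplus interval head (MSE on intervals normalized by the corpus mean).
Training uses truncated backpropagation through time over fixed windows,
Adam at learning rate 0.001, gradient-norm clipping at 5, up to 50 epochs
with early stopping (patience 5) on a 10% held-out window split. The
implementation is entirely in R; its analytic gradients are checked
against central finite differences (relative error < 1e-4) for both cell
types in the test suite. Training is deterministic given the config seed
under single-threaded BLAS.

Two scaling choices matter at desk scale. First, corpus size is data, not
a constant: validation trains on 2000-event corpora for 10 epochs with 32
hidden units and denser windowing (stride 4, batch 16) — small corpora
need more optimization steps per epoch, which smaller batches provide,
and 128 hidden units would be heavily over-parameterized for a 10-code
alphabet. Second, the interval branch predicts the conditional mean, so
generated interval *distributions* are narrower than the data; interval
fidelity is accordingly validated on same-distribution control pairs,
while generated-vs-training comparison uses the code-frequency chi-square.

Generation warm-starts the state on a seed slice of the corpus, then
samples types from the temperature-scaled softmax reweighted by the
statistical control `(target_freq / running_freq)^β` (add-half smoothing,
β = 1 by default) — a minimal mechanism that provably pulls empirical
frequencies toward the target. Intervals are floored at one sample period,
so positivity is absolute. Generation stops when every common code (top-k
by training frequency; all positive-frequency codes by default) has at
least 70 occurrences, or flags `capped` at the length limit.

`render_stimulus()` places code templates at the cumulative inter-peak
times on a zero baseline (overlap-added with a warning when intervals are
shorter than the template span). At zero noise, detection plus
classification recovers the (code, interval) sequence exactly, provided
the detection refractory covers the template span — rendered multiphasic
templates otherwise fire twice. Recovered event times are the re-centred
waveform peaks, which is what makes interval recovery sample-exact.

## Migration quantification

The CMC of one day's counts is `Σ i·CN_i·d / Σ CN_i` — the count-weighted
mean electrode position, with 1-based electrode indexing (electrode 1 sits
at distance d). It is bounded by `d ≤ CMC ≤ n·d`, shifts by exactly d
under a one-electrode translation of all cells, is invariant to count
scaling, and is *undefined* (NA, flagged) for an all-zero day — reporting
0 would fake a front regression. Condition comparison runs per-day paired
t-tests across replicate series with a Kolmogorov–Smirnov normality check
of the paired differences logged alongside; degenerate comparisons
(identical replicates) report t = 0, p = 1 rather than NaN.

## Problem sizes and numerical choices

Validation experiments use: 60 s × 8 channels for detection scoring
(≈56,000 ground-truth events), 100 two-second traces for the noise-SD MAE
comparison, 500 waveforms over 10 planted templates for codebook recovery,
2000-event corpora with 20 generation seeds for generator fidelity, and
100 random sequences for the render round trip. These sizes give stable
statistics while keeping any single experiment in the minutes range on one
CPU. Tolerances: refinement equals its brute-force oracle to 1e-12;
wavelet reconstruction to ~1e-11; EMD completeness to 1e-6 relative;
CMC to closed forms exactly.

## Command-line entry point

`inst/cli/neurocode` is a thin Rscript over the exported functions
(`simulate`, `detect`, `codebook`, `cmc`, `run`); `run_pipeline()` wires
all stages end to end on synthetic data, writes every artifact before the
next stage starts, and records an md5 manifest — reruns with the same seed
reproduce identical hashes.

## Known limitations

* The codebook is order-dependent (first-match-wins on a growing
  library); a different waveform order can yield a different library.
* The consistency metric saturates for windows much longer than the
  waveform; window choice is a real modelling decision.
* The interval branch of the generator reproduces conditional means, not
  interval variance; a distributional head (e.g. lognormal likelihood)
  would be the natural extension.
* Common-mode removal assumes many channels; with few channels it leaks
  signal across channels.
* EMD uses plain sifting; ensemble variants (EEMD) would be needed for
  heavily mode-mixed signals.
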