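# neurocode

Signal analysis for microelectrode-array (MEA) recordings of tumor–neural
interaction experiments: glioma cells co-cultured with neurons on a
32-electrode array (200 µm pitch, 30 kHz sampling), where neuronal
activity shapes tumor invasion and glioma cells in turn reshape the
neural signals. The package is aimed at electrophysiologists and
computational biologists who need the full chain from raw multichannel
voltage to interpretable statistics — and at anyone who wants a fully
seeded synthetic testbed for that chain.

## What it computes

* **Noise-robust spike detection.** The detection threshold is
  `AVG + factor·STD` (population statistics, factor 4 by default, 3–5
  conventional), *refined* by recomputing `AVG′`, `STD′` over the samples
  with `|x|` below the naive threshold, giving the modified threshold
  `AVG′ + factor·STD′`. Large spikes no longer inflate the noise
  estimate: the refined noise-SD estimate has strictly lower mean
  absolute error than the naive one on spike-contaminated traces.
* **Neural-code classification.** Detected waveforms are peak-aligned and
  classified against a growing template library: a waveform joins the
  first template whose per-sample consistency (deviations within 30% of
  the template peak) reaches 90%, otherwise it founds a new code.
  Recordings are summarized by code-frequency profiles and compared by
  chi-square.
* **Feature extraction.** Time-domain waveform properties (duration,
  rise/decay time, slope, dominant frequency), Welch band power with
  theta (4–8 Hz) and gamma (30–100 Hz) presets, Morlet wavelet band
  energies over 0.1–5 kHz, Hilbert–Huang (EMD) intrinsic-mode features,
  recursive feature elimination, and cross-validated shallow
  classification.
* **Stimulation-sequence generation.** A dual-branch recurrent model
  (2×128-unit LSTM, dropout 0.3, Adam 1e-3, multi-task loss: categorical
  cross-entropy on the next code type + MSE on the next inter-peak
  interval) learns recorded event sequences; a statistical control
  mechanism reweights generation toward the training code distribution
  until every common code has ≥70 occurrences. Generated sequences are
  validated by chi-square and Kolmogorov–Smirnov tests and rendered into
  stimulus waveforms that survive a detect→classify round trip exactly.
* **Invasion quantification.** The Cell Migration Center
  `CMC = Σ i·CN_i·d / Σ CN_i` — the count-weighted mean electrode
  position of the tumor population — with trajectories, normalized
  heatmaps, and paired per-day condition comparison.
* **Ground-truthed simulation.** `synth_recording()` generates recordings
  with known spike times (biphasic neuronal spikes, 1.2 ± 0.3 ms, mean
  interval 8.5 ms; multiphasic tumor potentials, 1–15.6 ms, interval CV
  32%; ±5 µV noise; shared 50 Hz + drift interference; optional
  cell–electrode coupling attenuation), plus event corpora and migration
  count tables.

## Worked example

```r
library(neurocode)

cfg <- sim_config(seed = 42, duration_s = 10, n_channels = 8)
sim <- synth_recording(cfg)
sim$recording
#> <mea_recording> 8 channel(s) x 300000 samples @ 30000 Hz (10.000 s), 0.195 uV/count

det <- detect_recording(sim$recording, factor = 4)
det$thresholds[[1]]
#> <mea_threshold> AVG 0.032, STD 7.653, factor 4 -> threshold 30.646 uV
#>   refined: AVG' 0.635, STD' 6.154 -> modified threshold 25.251 uV (5111 excluded)

score_detection(det$events, sim$events, tol_ms = 1, duration_s = 10)$f1
#> [1] 0.983
```

The refined threshold (25.3 µV) sits well below the naive one (30.6 µV):
excluding the 5111 supra-threshold samples removes the spikes'
contribution to the noise estimate. Against the simulator's ground truth
the detector recovers events with F1 = 0.983 at the default firing
statistics.

```r
wfs <- extract_waveforms(det$filtered$uv[1, ],
                         det$events[det$events$channel == 1, ], 30000)
cb <- build_codebook(wfs)
cb$library
#> <code_library> 5 code(s), tolerance 0.30, consistency >= 0.90
round(code_profile(cb$assignments, top_k = 3)$frequency[1:3], 3)
#>  C001  C002  C003
#> 0.978 0.017 0.003

cmc_timeseries(synth_migration("hyper", seed = 42))
#> <migration_result> [hyper]
#>    day cmc_um
#> 1 day1 1855.7
#> 2 day2 4721.8
#> 3 day3 5977.1
#> 4 day4 6111.8
#> ...
#> 7 day7 6129.9
```

One dominant code type (97.8% of events — the recording used a single
neuronal template) and a hyper-invasive CMC trajectory that reaches 99.7%
of its plateau by day 4.

`run_pipeline(demo_config(seed = 1), "out/")` wires every stage end to end
(simulate → detect → codebook → features → train → generate → validate →
render → migration) and writes an md5 manifest; reruns with the same seed
reproduce identical hashes. A thin CLI wrapper lives at
`inst/cli/neurocode`.

## Layout

```
R/            implementation (io, simulate, preprocess, detect, codebook,
              features, generate, migration, pipeline)
tests/        testthat suite incl. property-based acceptance checks
scripts/      acceptance.R
vignettes/    methods vignette (models, conventions, design choices)
inst/cli/     command-line wrapper
```
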