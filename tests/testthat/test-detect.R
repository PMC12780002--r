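# Threshold estimation (naive + refined), peak detection, waveform
# extraction. The refinement is checked against a brute-force loop oracle.

test_that("naive threshold matches hand-computed values", {
  expect_warning(est0 <- estimate_threshold(c(0, 0, 0, 0), factor = 4),
                 NA)  # factor 4 is in range: no warning
  expect_equal(est0$threshold_uv, 0)
  expect_true(est0$degenerate)
  est <- estimate_threshold(c(1, -1, 1, -1), factor = 3)
  expect_equal(est$avg_uv, 0)
  expect_equal(est$sd_uv, 1)  # population SD, divisor n
  expect_equal(est$threshold_uv, 3)
  expect_warning(estimate_threshold(rnorm(10), factor = 6), "range")
})

test_that("refinement equals the brute-force oracle on random traces", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(50:400, 1)
    trace <- rnorm(n, sd = runif(1, 0.5, 5))
    if (i %% 3 == 0) trace[sample(n, 3)] <- trace[sample(n, 3)] + 40
    f <- runif(1, 3, 5)
    got <- refine_threshold(trace, f)
    want <- brute_refine(trace, f)
    expect_equal(got$avg_refined_uv, want$avg_refined, tolerance = 1e-12)
    expect_equal(got$sd_refined_uv, want$sd_refined, tolerance = 1e-12)
    expect_equal(got$modified_threshold_uv, want$modified, tolerance = 1e-12)
    expect_equal(got$n_excluded, want$n_excluded)
    expect_lte(got$sd_refined_uv, got$sd_uv + 1e-12)
  }
})

test_that("refinement on the documented corner cases", {
  # trace [0,0,0,10], factor 3: naive 2.5 + 3*4.330 = 15.49; nothing
  # excluded, so modified equals naive recomputation over all samples
  got <- refine_threshold(c(0, 0, 0, 10), factor = 3)
  expect_equal(got$threshold_uv, 2.5 + 3 * sqrt(mean((c(0, 0, 0, 10) - 2.5)^2)))
  expect_equal(got$n_excluded, 0L)
  expect_equal(got$modified_threshold_uv, got$threshold_uv)
  # pure noise: refinement moves the threshold by < 5%
  set.seed(21)
  tr <- rnorm(30000)
  got <- refine_threshold(tr, 4)
  expect_lt(abs(got$modified_threshold_uv - got$threshold_uv) /
              got$threshold_uv, 0.05)
  # spiky trace: refinement strictly lowers the threshold
  tr2 <- tr
  tr2[sample(30000, 300)] <- tr2[sample(30000, 300)] + 30
  got2 <- refine_threshold(tr2, 4)
  expect_lt(got2$modified_threshold_uv, got2$threshold_uv)
})

test_that("refined SD tracks the true noise SD better than the naive SD", {
  set.seed(22)
  mae_naive <- mae_ref <- numeric(100)
  for (s in 1:100) {
    tr <- rnorm(20000, sd = 2.4)
    spikes <- sample(19000, 100)
    for (i in spikes) tr[i:(i + 10)] <- tr[i:(i + 10)] +
        19.2 * sin(pi * (1:11) / 12)
    est <- refine_threshold(tr, 4)
    mae_naive[s] <- abs(est$sd_uv - 2.4)
    mae_ref[s] <- abs(est$sd_refined_uv - 2.4)
  }
  expect_lt(mean(mae_ref), mean(mae_naive))
})

test_that("peak detection respects threshold, polarity and refractory", {
  fs <- 30000
  tr <- numeric(3000)
  tr[1000] <- -50; tr[1015] <- -40   # 0.5 ms apart
  tr[2000] <- 30
  ev <- detect_peaks(tr, 20, fs, refractory_ms = 2)
  expect_equal(nrow(ev), 2)   # refractory merges the first pair
  expect_equal(ev$amplitude_uv, c(-50, 30))
  ev_neg <- detect_peaks(tr, 20, fs, refractory_ms = 2, polarity = "negative")
  expect_equal(nrow(ev_neg), 1)
  expect_equal(detect_peaks(numeric(), 20, fs)$channel, integer())
  # monotonicity: a higher factor never yields more events
  set.seed(23)
  noisy <- rnorm(30000, sd = 2)
  noisy[seq(500, 29500, by = 600)] <- noisy[seq(500, 29500, by = 600)] - 15
  counts <- vapply(c(3, 3.5, 4, 4.5, 5), function(f) {
    th <- refine_threshold(noisy, f)
    nrow(detect_peaks(noisy, th, fs))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("detection achieves F1 >= 0.95 on simulated spikes at SNR >= 5", {
  # common-mode subtraction needs enough channels that spike leakage into
  # the channel mean stays below threshold; the array has 32, tests use 8
  cfg <- sim_config(seed = 24, duration_s = 6, n_channels = 8,
                    neuron_amplitude_uv = 12, amplitude_jitter = 0,
                    tumor_rate_hz = 0)   # SNR 5 at noise SD 2.4
  sim <- synth_recording(cfg)
  # short recordings leave the one-pass threshold noisy; iterate to the
  # stable exclusion set (the acceptance-scale 60 s run uses one pass)
  det <- detect_recording(sim$recording, factor = 4, iterate = TRUE)
  sc <- score_detection(det$events, sim$events, tol_ms = 1,
                        duration_s = 6)
  expect_gte(sc$f1, 0.95)
})

test_that("waveform extraction aligns peaks and drops truncated windows", {
  fs <- 30000
  tr <- rnorm(3000, sd = 0.1)
  tr[1000] <- -40
  ev <- event_table(1L, (1000 - 1) / fs, NA, -40)
  wf <- extract_waveforms(tr, ev, fs, window_ms = 2)
  expect_equal(length(wf), 1)
  expect_equal(length(wf[[1]]$samples_uv), 61)   # 2 ms total at 30 kHz
  expect_equal(wf[[1]]$alignment_index, 31L)
  expect_equal(abs(wf[[1]]$samples_uv[31]), max(abs(wf[[1]]$samples_uv)))
  # event too close to the trace end is dropped with a warning
  ev2 <- event_table(1L, (2995 - 1) / fs, NA, 1)
  expect_warning(wf2 <- extract_waveforms(tr, ev2, fs, window_ms = 2),
                 "dropped")
  expect_equal(length(wf2), 0)
})

test_that("extracted snippets correlate with their source templates", {
  tpl <- synth_templates(seed = 25)[[1]]
  cfg <- sim_config(seed = 25, duration_s = 5, n_channels = 1,
                    neuron_amplitude_uv = 12, templates = list(tpl),
                    tumor_rate_hz = 0, common_mode_amplitude_uv = 0,
                    drift_amplitude_uv = 0)
  sim <- synth_recording(cfg)
  filt <- preprocess_recording(sim$recording, "detect")
  det <- detect_recording(filt)
  wfs <- suppressWarnings(
    extract_waveforms(filt$uv[1, ], det$events, 30000, window_ms = 2))
  half <- 30
  ref <- neurocode:::conform_waveform(12 * tpl$shape, tpl$alignment_index,
                                      61, 31)
  cors <- vapply(wfs, function(w) cor(w$samples_uv, ref), 0)
  expect_gt(mean(cors >= 0.9), 0.9)
})
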