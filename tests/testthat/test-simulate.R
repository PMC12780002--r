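# Synthetic-data generator: template morphology, coupling circuit,
# recording statistics, corpora and migration tables.

count_lobes <- function(shape, min_frac = 0.2) {
  # significant sign-alternating lobes: contiguous same-sign runs whose
  # extremum reaches min_frac of the peak
  s <- sign(shape)
  runs <- rle(s[s != 0])
  peaks <- abs(shape)
  idx <- cumsum(c(0, runs$lengths))
  vals <- vapply(seq_along(runs$lengths), function(i) {
    seg <- shape[s != 0][(idx[i] + 1):idx[i + 1]]
    max(abs(seg))
  }, 0)
  sig <- vals >= min_frac * max(peaks)
  sum(rle(runs$values[sig])$lengths > 0)
}

test_that("neuronal templates are biphasic with in-range durations", {
  tpls <- synth_templates(n_neuronal = 20, seed = 1)
  for (tpl in tpls) {
    expect_equal(tpl$kind, "neuronal")
    expect_gte(tpl$duration_ms, 0.9)
    expect_lte(tpl$duration_ms, 1.5)
    # exactly two lobes of opposite sign
    expect_equal(count_lobes(tpl$shape), 2)
    expect_lt(min(tpl$shape), 0)
    expect_gt(max(tpl$shape), 0)
    # unit peak at the declared (strict) alignment index
    expect_equal(abs(tpl$shape[tpl$alignment_index]), max(abs(tpl$shape)))
    expect_equal(sum(abs(abs(tpl$shape) - max(abs(tpl$shape))) < 1e-12), 1)
  }
})

test_that("tumor templates are multiphasic with durations in 1-15.6 ms", {
  tpls <- synth_templates(n_neuronal = 0, n_tumor = 20, seed = 2)
  for (tpl in tpls) {
    expect_equal(tpl$kind, "tumor")
    expect_gte(tpl$duration_ms, 1)
    expect_lte(tpl$duration_ms, 15.6)
    expect_gte(count_lobes(tpl$shape), 3)
  }
  expect_error(synth_templates(neuronal_duration_ms = c(0, 0.1)),
               "config error")
})

test_that("coupling ratio behaves as a seal-resistance voltage divider", {
  base <- list(membrane_resistance_ohm = 1e8, membrane_capacitance_f = 1e-11,
               electrode_impedance_ohm = 1e6)
  r_inf <- do.call(coupling_ratio, c(list(r_seal_ohm = 1e15), base))
  r_zero <- do.call(coupling_ratio, c(list(r_seal_ohm = 1e-3), base))
  expect_gt(r_inf, 0.999999)
  expect_lt(r_zero, 1e-6)
  # strict monotonicity in r_seal over a wide sweep
  rs <- 10^seq(4, 10, length.out = 25)
  vals <- vapply(rs, function(r)
    do.call(coupling_ratio, c(list(r_seal_ohm = r), base)), 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals <= 1))
  # doubling r_seal from a finite value strictly increases the ratio
  expect_gt(do.call(coupling_ratio, c(list(r_seal_ohm = 2e6), base)),
            do.call(coupling_ratio, c(list(r_seal_ohm = 1e6), base)))
  expect_error(coupling_ratio(-1), "config error")
})

test_that("recordings are reproducible and carry exact ground truth", {
  cfg <- sim_config(seed = 7, duration_s = 2, n_channels = 2)
  a <- synth_recording(cfg)
  b <- synth_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events$time_s, b$events$time_s)
  expect_gt(nrow(a$events), 0)
  expect_true(all(a$events$code_id == "N01"))
})

test_that("noise-only recordings match the configured noise SD", {
  cfg <- sim_config(seed = 8, duration_s = 2, n_channels = 1,
                    neuron_rate_hz = 0, common_mode_amplitude_uv = 0,
                    drift_amplitude_uv = 0)
  sim <- synth_recording(cfg)
  expect_equal(nrow(sim$events), 0)
  expect_lt(abs(sd(as_uv(sim$recording)[1, ]) - cfg$noise_sd_uv) /
              cfg$noise_sd_uv, 0.1)
})

test_that("neuronal inter-peak intervals track the 8.5 ms target", {
  cfg <- sim_config(seed = 9, duration_s = 60, n_channels = 1,
                    noise_sd_uv = 0.01, common_mode_amplitude_uv = 0,
                    drift_amplitude_uv = 0)
  sim <- synth_recording(cfg)
  iv <- diff(sim$events$time_s) * 1000
  expect_lt(abs(mean(iv) - 8.5) / 8.5, 0.2)
  expect_true(all(iv >= cfg$refractory_ms - 1e-9))
})

test_that("tumor interval CV matches the configured 32%", {
  set.seed(10)
  t <- neurocode:::gamma_interval_times(10, 0.32, 200)
  iv <- diff(t)
  expect_lt(abs(sd(iv) / mean(iv) - 0.32), 0.05)
})

test_that("coupling attenuation scales inserted amplitudes exactly", {
  cpl <- list(r_seal_ohm = 5e6)
  ratio <- do.call(coupling_ratio, cpl)
  cfg <- sim_config(seed = 11, duration_s = 2, n_channels = 1,
                    noise_sd_uv = 1e-6, amplitude_jitter = 0,
                    common_mode_amplitude_uv = 0, drift_amplitude_uv = 0,
                    coupling = cpl)
  sim <- synth_recording(cfg)
  expect_gt(nrow(sim$events), 0)
  expect_equal(max(abs(sim$events$amplitude_uv)),
               cfg$neuron_amplitude_uv * ratio, tolerance = 1e-6)
})

test_that("event corpora converge to the requested code distribution", {
  p <- c(A = 0.25, B = 0.25, C = 0.25, D = 0.25)
  corpus <- synth_event_corpus(p, 10000, seed = 12)
  f <- table(corpus[[1]]$code_id) / 10000
  expect_true(all(abs(f - 0.25) < 0.02))
  expect_true(all(corpus[[1]]$interval_ms > 0))
  # single code type
  one <- synth_event_corpus(c(X = 1), 50, seed = 13)
  expect_true(all(one[[1]]$code_id == "X"))
  # n = 0 and config errors
  expect_equal(length(synth_event_corpus(p, 0, seed = 1)), 0)
  expect_error(synth_event_corpus(numeric(), 10), "empty")
  expect_error(synth_event_corpus(c(A = 0.5, B = 0.4), 10), "sum to 1")
})

test_that("migration tables have the required front shapes", {
  hy <- cmc_timeseries(synth_migration("hyper", seed = 3))
  no <- cmc_timeseries(synth_migration("normal", seed = 3))
  expect_true(all(diff(hy$cmc_um) >= 0))
  expect_gte(hy$cmc_um[4], 0.9 * hy$cmc_um[7])
  expect_true(all(hy$cmc_um[2:7] > no$cmc_um[2:7]))
  single <- synth_migration("hyper", n_days = 1, seed = 4)
  expect_equal(nrow(single$counts), 1)
  expect_true(all(synth_migration("normal", seed = 5)$counts >= 0))
  expect_error(synth_migration("hyper", n_days = 0), "config error")
})
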