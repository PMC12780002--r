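# Feature extraction: time-domain waveform properties, Welch band power,
# Morlet energies, EMD/Hilbert features, RFE and shallow classification.

test_that("waveform properties follow the documented conventions", {
  fs <- 30000
  # symmetric triangular pulse: rise equals decay
  tri <- c(seq(0, 1, length.out = 31), seq(1, 0, length.out = 31)[-1])
  p <- waveform_properties(tri, fs)
  expect_equal(p$rise_time_ms, p$decay_time_ms, tolerance = 1e-9)
  # amplitude scaling leaves time properties unchanged
  p2 <- waveform_properties(2 * tri, fs)
  expect_equal(p$duration_ms, p2$duration_ms)
  expect_equal(p$rise_time_ms, p2$rise_time_ms)
  expect_equal(2 * p$amplitude_uv, p2$amplitude_uv)
  # simulated neuronal template durations stay in the 0.9-1.5 ms band
  for (tpl in synth_templates(n_neuronal = 10, seed = 41)) {
    pp <- waveform_properties(40 * tpl$shape, fs)
    expect_gte(pp$duration_ms, 0.7)
    expect_lte(pp$duration_ms, 1.6)
  }
  pf <- waveform_properties(numeric(31), fs)
  expect_true(pf$flat)
})

test_that("band power lands tones in their bands", {
  fs <- 1000
  t <- seq_len(10 * fs) / fs
  expect_gte(band_power(sin(2 * pi * 6 * t), fs, "theta",
                        total_band = c(1, 150))$fraction, 0.95)
  expect_gte(band_power(sin(2 * pi * 50 * t), fs, "gamma",
                        total_band = c(1, 150))$fraction, 0.95)
  # white noise: fraction approximates the bandwidth ratio
  set.seed(42)
  frac <- band_power(rnorm(10 * fs), fs, "gamma",
                     total_band = c(1, 150))$fraction
  bw <- (100 - 30) / 149
  expect_lt(abs(frac - bw) / bw, 0.2)
  # amplitude invariance of the fraction
  x <- sin(2 * pi * 6 * t) + 0.5 * sin(2 * pi * 60 * t)
  expect_equal(band_power(x, fs, "theta")$fraction,
               band_power(3 * x, fs, "theta")$fraction, tolerance = 1e-9)
  expect_error(band_power(x, fs, c(400, 600)), "Nyquist")
})

test_that("Morlet energies localize tones and scale quadratically", {
  fs <- 30000
  t <- seq_len(fs / 2) / fs
  tone <- sin(2 * pi * 1000 * t)
  e <- morlet_energies(tone, fs)
  band <- which.max(e)
  edges <- exp(seq(log(100), log(5000), length.out = 9))
  expect_gte(1000, edges[band])
  expect_lte(1000, edges[band + 1])
  expect_equal(unname(morlet_energies(2 * tone, fs) / e), rep(4, 8),
               tolerance = 1e-6)
  expect_equal(unname(morlet_energies(numeric(1000), fs)), rep(0, 8))
  expect_error(morlet_energies(tone, fs, band_edges = c(100, 20000)),
               "config error")
})

test_that("EMD is complete and separates a two-tone signal", {
  fs <- 2000
  t <- seq_len(2 * fs) / fs
  x <- sin(2 * pi * 5 * t) + 0.8 * sin(2 * pi * 200 * t)
  dec <- emd(x)
  expect_lt(max(abs(colSums(dec$imfs) + dec$residual - x)) /
              max(abs(x)), 1e-6)
  h <- hht_features(x, fs)
  # the two dominant IMFs carry ~all energy and sit near 200 and 5 Hz
  en <- h[grep("energy", names(h))]
  top2 <- order(en, decreasing = TRUE)[1:2]
  mifs <- sort(h[paste0("imf", top2, "_mif_hz")])
  expect_lt(abs(mifs[1] - 5) / 5, 0.2)
  expect_lt(abs(mifs[2] - 200) / 200, 0.2)
  # a pure tone concentrates energy in the first IMF
  tone <- sin(2 * pi * 50 * t)
  ht <- hht_features(tone, fs)
  et <- ht[grep("energy", names(ht))]
  expect_gte(et[1] / sum(et), 0.9)
  # completeness on rough noise too
  set.seed(43)
  noisy <- rnorm(512)
  dn <- emd(noisy)
  expect_lt(max(abs(colSums(dn$imfs) + dn$residual - noisy)) /
              max(abs(noisy)), 1e-6)
  expect_error(emd(rnorm(32)), "config error")
})

test_that("feature extraction is deterministic", {
  fs <- 2000
  x <- sin(2 * pi * 7 * seq_len(1000) / fs) + 0.1 * cos(2 * pi * 90 * seq_len(1000) / fs)
  expect_identical(hht_features(x, fs), hht_features(x, fs))
  expect_identical(morlet_energies(x, fs, band_edges = c(5, 50, 500)),
                   morlet_energies(x, fs, band_edges = c(5, 50, 500)))
})

test_that("RFE keeps informative features and drops noise", {
  hits <- 0
  for (s in 1:50) {
    set.seed(100 + s)
    n <- 60
    y <- rep(c("a", "b"), each = n / 2)
    x <- matrix(rnorm(n * 22), n)
    colnames(x) <- c("inf1", "inf2", sprintf("noise%02d", 1:20))
    x[, 1] <- x[, 1] + ifelse(y == "a", 2, -2)
    x[, 2] <- x[, 2] + ifelse(y == "a", -2, 2)
    sel <- rfe_select(x, y, k = 2)
    hits <- hits + setequal(sel, c("inf1", "inf2"))
  }
  expect_gte(hits / 50, 0.95)
  # identity when k equals the number of features
  set.seed(44)
  x <- matrix(rnorm(40), 10); colnames(x) <- letters[1:4]
  expect_equal(rfe_select(x, rep(c("a", "b"), 5), k = 4), letters[1:4])
  expect_error(rfe_select(x, rep("a", 10), k = 2), "2 classes")
})

test_that("cross-validated classification separates template classes", {
  # features from neuronal vs tumor templates at SNR 10
  set.seed(45)
  fs <- 30000
  tpls <- synth_templates(n_neuronal = 6, n_tumor = 6, seed = 45)
  rows <- list(); labs <- character()
  for (i in 1:120) {
    tpl <- tpls[[((i - 1) %% 12) + 1]]
    w <- neurocode:::conform_waveform(40 * tpl$shape, tpl$alignment_index,
                                      121, 61)
    w <- wavelet_denoise(w + rnorm(121, 0, 4))   # denoise before features
    p <- waveform_properties(w, fs)
    rows[[i]] <- c(duration = p$duration_ms, rise = p$rise_time_ms,
                   decay = p$decay_time_ms, slope = p$slope_uv_per_ms,
                   integral = p$interval_integral, freq = p$frequency_hz,
                   morlet_energies(w, fs))
    labs[i] <- tpl$kind
  }
  x <- do.call(rbind, rows)
  res <- classify_signals(x, labs, folds = 5, seed = 45)
  expect_gte(res$accuracy, 0.95)
  # shuffled labels fall to chance
  set.seed(46)
  res0 <- classify_signals(x, sample(labs), folds = 5, seed = 46)
  expect_lt(abs(res0$accuracy - 0.5), 0.15)
  expect_error(classify_signals(x[1:2, ], c("a", "b"), folds = 5), "folds")
})
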