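# Time-domain waveform properties, Welch band power, Morlet band energies,
# Hilbert-Huang (EMD) features, recursive feature elimination and a shallow
# cross-validated classifier over the resulting feature vectors.

# linear-interpolated crossing time (in samples, 1-based fractional)
cross_time <- function(x, idx_from, idx_to, level) {
  # scan from idx_from toward idx_to for the first crossing of `level`
  step <- sign(idx_to - idx_from)
  prev <- idx_from
  for (i in seq(idx_from + step, idx_to, by = step)) {
    a <- x[prev]; b <- x[i]
    if ((a - level) * (b - level) <= 0 && a != b)
      return(prev + step * (level - a) / (b - a) * 1)
    prev <- i
  }
  idx_to
}

#' Time-domain properties of a peak-aligned waveform
#'
#' Conventions (documented, not universal): duration is the span where
#' `|x|` is at least 10% of the peak magnitude (first to last crossing);
#' rise time is 10% -> 90% of peak magnitude on the leading edge, decay
#' time 90% -> 10% on the trailing edge, both with linear sub-sample
#' interpolation; slope is the maximum absolute sample-to-sample derivative;
#' `interval_integral` is the area under `|x|` between the duration
#' endpoints; `frequency_hz` is the dominant spectral peak of the snippet.
#' All time properties are invariant to amplitude scaling.
#'
#' @param waveform an `mea_waveform` or numeric vector (uV).
#' @param rate sampling rate (Hz).
#' @return list of class `waveform_properties`: `amplitude_uv`,
#'   `duration_ms`, `rise_time_ms`, `decay_time_ms`, `slope_uv_per_ms`,
#'   `interval_integral`, `frequency_hz`, `flat` (degenerate flag).
#' @export
waveform_properties <- function(waveform, rate) {
  x <- if (inherits(waveform, "mea_waveform")) waveform$samples_uv else waveform
  n <- length(x)
  pk_i <- which.max(abs(x))
  pk <- abs(x[pk_i])
  if (pk == 0) {
    return(structure(list(amplitude_uv = 0, duration_ms = NA_real_,
                          rise_time_ms = NA_real_, decay_time_ms = NA_real_,
                          slope_uv_per_ms = 0, interval_integral = 0,
                          frequency_hz = NA_real_, flat = TRUE),
                     class = "waveform_properties"))
  }
  a <- abs(x)
  lo <- 0.1 * pk; hi <- 0.9 * pk
  above <- which(a >= lo)
  i_first <- above[1]; i_last <- above[length(above)]
  t10_lead <- if (i_first > 1) cross_time(a, i_first, i_first - 1, lo) else 1
  t10_trail <- if (i_last < n) cross_time(a, i_last, i_last + 1, lo) else n
  t90_lead <- cross_time(a, pk_i, max(pk_i - 1, 1), hi)
  t90_trail <- cross_time(a, pk_i, min(pk_i + 1, n), hi)
  ms <- 1000 / rate
  dur <- (t10_trail - t10_lead) * ms
  rise <- (t90_lead - t10_lead) * ms
  decay <- (t10_trail - t90_trail) * ms
  slope <- max(abs(diff(x))) / ms
  seg <- x[ceiling(t10_lead):floor(t10_trail)]
  integral <- sum(abs(seg)) / rate
  freq <- if (n >= 8) {
    sp <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]
    (which.max(sp) - 1) * rate / n
  } else NA_real_
  structure(list(amplitude_uv = x[pk_i], duration_ms = dur,
                 rise_time_ms = rise, decay_time_ms = decay,
                 slope_uv_per_ms = slope, interval_integral = integral,
                 frequency_hz = freq, flat = FALSE),
            class = "waveform_properties")
}

# Hann-windowed Welch power spectral density; returns freq (Hz) and psd
welch_psd <- function(x, rate, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, max(256L, 2^floor(log2(n / 4))))
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(win^2)
  acc <- numeric(floor(nperseg / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(stats::fft(seg))^2
    acc <- acc + sp[seq_along(acc)]
  }
  psd <- acc / (length(starts) * u * rate)
  # one-sided: double everything except DC (and Nyquist for even nperseg)
  psd[-1] <- 2 * psd[-1]
  if (nperseg %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  list(freq = (seq_along(psd) - 1) * rate / nperseg, psd = psd)
}

#' Band power and band-power fraction
#'
#' Welch spectral estimate integrated over a frequency band. Named presets:
#' `"theta"` = 4-8 Hz, `"gamma"` = 30-100 Hz. The fraction is relative to
#' `total_band` (default: the full spectrum up to Nyquist) and is invariant
#' to amplitude scaling.
#'
#' @param trace numeric vector (uV).
#' @param rate sampling rate (Hz).
#' @param band numeric `c(low, high)` in Hz, or `"theta"` / `"gamma"`.
#' @param total_band reference band for the fraction (Hz).
#' @param nperseg Welch segment length (`NULL` = automatic).
#' @return list: `power` (uV^2), `fraction`, `band`.
#' @export
band_power <- function(trace, rate, band, total_band = NULL, nperseg = NULL) {
  if (is.character(band))
    band <- switch(match.arg(band, c("theta", "gamma")),
                   theta = c(4, 8), gamma = c(30, 100))
  if (band[2] > rate / 2)
    stop("band_power: config error: band above Nyquist")
  if (length(trace) < 2 * rate / band[1])
    stop("band_power: trace shorter than 2 periods of the band low edge")
  w <- welch_psd(trace, rate, nperseg)
  integ <- function(b) {
    sel <- w$freq >= b[1] & w$freq <= b[2]
    if (!any(sel)) return(0)
    sum(w$psd[sel]) * (w$freq[2] - w$freq[1])
  }
  p <- integ(band)
  tot <- if (is.null(total_band)) integ(c(0, rate / 2)) else integ(total_band)
  list(power = p, fraction = if (tot > 0) p / tot else NA_real_, band = band)
}

#' Morlet wavelet band energies
#'
#' Continuous wavelet transform with an analytic Morlet mother wavelet
#' (centre frequency parameter `omega0 = 6`), evaluated at log-spaced
#' frequencies within each band; the energy of a band is the mean squared
#' transform magnitude. Default: 8 logarithmic bands spanning 0.1-5 kHz.
#' Energies are non-negative and scale quadratically with amplitude.
#'
#' @param trace numeric vector (uV).
#' @param rate sampling rate (Hz).
#' @param band_edges increasing vector of band edges in Hz (length
#'   `n_bands + 1`); must lie in (0, Nyquist).
#' @param omega0 Morlet centre-frequency parameter.
#' @param freqs_per_band CWT evaluation frequencies per band.
#' @return named numeric vector of band energies.
#' @export
morlet_energies <- function(trace, rate,
                            band_edges = exp(seq(log(100), log(5000),
                                                 length.out = 9)),
                            omega0 = 6, freqs_per_band = 3) {
  if (any(band_edges <= 0) || any(band_edges >= rate / 2))
    stop("morlet_energies: config error: band edges outside (0, Nyquist)")
  if (is.unsorted(band_edges, strictly = TRUE))
    stop("morlet_energies: config error: band edges must be increasing")
  n <- length(trace)
  xf <- stats::fft(trace)
  w <- 2 * pi * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
  nb <- length(band_edges) - 1
  out <- stats::setNames(numeric(nb),
                         sprintf("morlet_%0.0f_%0.0fHz",
                                 band_edges[-(nb + 1)], band_edges[-1]))
  for (b in seq_len(nb)) {
    fc <- exp(seq(log(band_edges[b]), log(band_edges[b + 1]),
                  length.out = freqs_per_band + 2))[2:(freqs_per_band + 1)]
    e <- 0
    for (f in fc) {
      s <- omega0 / (2 * pi * f)                 # scale in seconds
      psi <- pi^(-0.25) * exp(-(s * w - omega0)^2 / 2) * (w > 0)
      wt <- stats::fft(xf * psi, inverse = TRUE) / n
      e <- e + mean(Mod(wt)^2)
    }
    out[b] <- e / length(fc)
  }
  out
}

# local extrema indices (strict on the right to break plateaus)
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(), min = integer()))
  core <- 2:(n - 1)
  list(max = core[x[core] >= x[core - 1] & x[core] > x[core + 1]],
       min = core[x[core] <= x[core - 1] & x[core] < x[core + 1]])
}

# spline envelope through extrema, with two mirrored extrema at each end
spline_envelope <- function(idx, val, n) {
  if (length(idx) < 2) return(rep(mean(val), n))
  k <- min(2, length(idx) - 1)
  left_i <- 2 * idx[1] - idx[(k + 1):2]
  left_v <- val[(k + 1):2]
  right_i <- 2 * idx[length(idx)] - idx[(length(idx) - 1):(length(idx) - k)]
  right_v <- val[(length(idx) - 1):(length(idx) - k)]
  stats::spline(c(left_i, idx, right_i), c(left_v, val, right_v),
                xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Standard sifting: cubic-spline upper/lower envelopes through local
#' extrema (mirrored at the edges), iterated until the Cauchy stopping
#' criterion falls below `sd_stop` or `max_sift` passes. Extraction stops
#' when the residual has fewer than 2 maxima or minima, or at `max_imfs`.
#' The decomposition is complete by construction: the returned residual is
#' `x - rowSums(imfs)` exactly.
#'
#' @param x numeric vector, length >= 64.
#' @param max_imfs maximum number of intrinsic mode functions.
#' @param sd_stop Cauchy sifting threshold.
#' @param max_sift sifting iteration cap (non-convergent sifting is capped
#'   and flagged).
#' @return list: `imfs` (matrix, one IMF per row), `residual`, `capped`.
#' @export
emd <- function(x, max_imfs = 8, sd_stop = 0.05, max_sift = 50) {
  if (length(x) < 64) stop("emd: config error: trace length must be >= 64")
  n <- length(x)
  imfs <- list(); res <- x; capped <- FALSE
  for (k in seq_len(max_imfs)) {
    ex <- local_extrema(res)
    if (length(ex$max) < 2 || length(ex$min) < 2) break
    h <- res
    for (s in seq_len(max_sift)) {
      ex <- local_extrema(h)
      if (length(ex$max) < 2 || length(ex$min) < 2) break
      upper <- spline_envelope(ex$max, h[ex$max], n)
      lower <- spline_envelope(ex$min, h[ex$min], n)
      m <- (upper + lower) / 2
      h_new <- h - m
      crit <- sum(m^2) / max(sum(h^2), 1e-300)
      h <- h_new
      if (crit < sd_stop) break
      if (s == max_sift) capped <- TRUE
    }
    imfs[[k]] <- h
    res <- res - h
  }
  if (!length(imfs))
    return(list(imfs = matrix(numeric(), 0, n), residual = x, capped = capped))
  im <- do.call(rbind, imfs)
  list(imfs = im, residual = x - colSums(im), capped = capped)
}

# analytic signal via FFT (Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# amplitude-weighted mean instantaneous frequency (Hz), edges trimmed
mean_instantaneous_freq <- function(x, rate, trim = 0.1) {
  z <- analytic_signal(x)
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi   # unwrap step
  fi <- dph * rate / (2 * pi)
  amp2 <- (Mod(z)[-1])^2
  n <- length(fi)
  keep <- max(1, floor(trim * n)):ceiling((1 - trim) * n)
  sum(fi[keep] * amp2[keep]) / sum(amp2[keep])
}

#' Sample entropy
#'
#' SampEn(m, r): negative log conditional probability that sequences close
#' for `m` points remain close for `m + 1`. Traces longer than `max_n` are
#' decimated for tractability.
#'
#' @param x numeric vector.
#' @param m embedding dimension.
#' @param r tolerance as a fraction of the trace SD.
#' @param max_n decimation cap.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, max_n = 1000) {
  n <- length(x)
  if (n > max_n) x <- x[seq(1, n, length.out = max_n)]
  n <- length(x)
  sdx <- stats::sd(x)
  if (sdx == 0) return(0)
  tol <- r * sdx
  count_pairs <- function(mm) {
    emb <- stats::embed(x, mm)       # rows are length-mm windows (reversed)
    np <- nrow(emb)
    cnt <- 0
    for (i in seq_len(np - 1)) {
      d <- abs(emb[(i + 1):np, , drop = FALSE] -
                 matrix(emb[i, ], np - i, mm, byrow = TRUE))
      cnt <- cnt + sum(apply(d, 1, max) <= tol)
    }
    cnt
  }
  B <- count_pairs(m); A <- count_pairs(m + 1)
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

#' Hilbert-Huang features of a trace
#'
#' Decomposes the trace into intrinsic mode functions ([emd()]) and emits,
#' per IMF: energy, amplitude-weighted mean instantaneous frequency (via
#' the Hilbert transform), and sample entropy. A fixed, documented feature
#' order; deterministic for a given trace.
#'
#' @param trace numeric vector, length >= 64.
#' @param rate sampling rate (Hz).
#' @param max_imfs maximum IMFs (vector padded with zeros/NA beyond the
#'   decomposition depth so feature length is fixed).
#' @return named numeric vector of length `3 * max_imfs`, plus attribute
#'   `"emd"` with the decomposition.
#' @export
hht_features <- function(trace, rate, max_imfs = 4) {
  dec <- emd(trace, max_imfs = max_imfs)
  k <- nrow(dec$imfs)
  out <- numeric(3 * max_imfs)
  names(out) <- as.vector(t(outer(seq_len(max_imfs), c("energy", "mif_hz", "sampen"),
                                  function(i, s) sprintf("imf%d_%s", i, s))))
  for (i in seq_len(k)) {
    im <- dec$imfs[i, ]
    out[3 * i - 2] <- sum(im^2)
    out[3 * i - 1] <- mean_instantaneous_freq(im, rate)
    out[3 * i] <- sample_entropy(im)
  }
  attr(out, "emd") <- dec
  out
}

# ridge-regularized linear discriminant: returns per-feature importance
# (sum of |discriminant coefficients| over classes) and a predictor
rlda_fit <- function(x, y, lambda = 1e-3) {
  x <- as.matrix(x)
  cls <- sort(unique(y))
  if (length(cls) < 2) stop("rlda: need >= 2 classes")
  mu <- t(vapply(cls, function(c) colMeans(x[y == c, , drop = FALSE]),
                 numeric(ncol(x))))
  xc <- x - mu[match(y, cls), , drop = FALSE]
  S <- crossprod(xc) / (nrow(x) - length(cls))
  S <- S + diag(lambda * mean(diag(S)) + 1e-12, ncol(x))
  Sinv <- solve(S)
  W <- Sinv %*% t(mu)                       # one column per class
  b <- -0.5 * colSums(t(mu) * W) + log(1 / length(cls))
  list(classes = cls, W = W, b = b,
       importance = rowSums(abs(W)))
}

rlda_predict <- function(fit, x) {
  sc <- as.matrix(x) %*% fit$W + matrix(fit$b, nrow(as.matrix(x)),
                                        length(fit$classes), byrow = TRUE)
  fit$classes[max.col(sc, ties.method = "first")]
}

#' Recursive feature elimination
#'
#' Iteratively drops the feature with the smallest importance under a
#' ridge-regularized linear discriminant scorer until `k` features remain.
#' Deterministic: no random draws.
#'
#' @param feature_matrix numeric matrix or data.frame (rows = samples,
#'   named columns = features).
#' @param labels class labels (>= 2 classes).
#' @param k number of features to keep (default 12).
#' @return character vector of selected feature names, in original column
#'   order.
#' @export
rfe_select <- function(feature_matrix, labels, k = 12) {
  x <- as.matrix(feature_matrix)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  if (length(unique(labels)) < 2)
    stop("rfe_select: need at least 2 classes")
  if (k >= ncol(x)) {
    if (k > ncol(x))
      warning("rfe_select: k >= number of features; returning all")
    return(colnames(x))
  }
  # standardize so importance is scale-free
  x <- scale(x)
  x[is.nan(x)] <- 0
  keep <- colnames(x)
  while (length(keep) > k) {
    fit <- rlda_fit(x[, keep, drop = FALSE], labels)
    drop <- keep[which.min(fit$importance)]
    keep <- setdiff(keep, drop)
  }
  keep[order(match(keep, colnames(x)))]
}

#' Cross-validated shallow classification
#'
#' Seeded stratified k-fold cross-validation with a pluggable classifier
#' (default: the package's ridge-regularized linear discriminant). Reports
#' overall accuracy and a per-class recall table.
#'
#' @param feature_matrix numeric matrix (rows = samples).
#' @param labels class labels.
#' @param folds number of folds (must not exceed the smallest class count).
#' @param seed fold-assignment seed.
#' @param classifier function `(train_x, train_y, test_x) -> predicted`;
#'   `NULL` uses the built-in discriminant.
#' @return list: `accuracy`, `per_class` (named recall), `confusion`,
#'   `fold_accuracy`.
#' @export
classify_signals <- function(feature_matrix, labels, folds = 5, seed = 1,
                             classifier = NULL) {
  x <- as.matrix(feature_matrix)
  labels <- as.character(labels)
  cls_n <- table(labels)
  if (folds > min(cls_n))
    stop("classify_signals: folds exceed the smallest class count")
  if (max(cls_n) > 3 * min(cls_n))
    warning("classify_signals: classes are strongly unbalanced")
  if (is.null(classifier))
    classifier <- function(tx, ty, sx) rlda_predict(rlda_fit(tx, ty), sx)
  set.seed(seed)
  fold <- integer(length(labels))
  for (c in names(cls_n)) {
    idx <- which(labels == c)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  pred <- character(length(labels))
  facc <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fold == f
    pred[te] <- classifier(x[!te, , drop = FALSE], labels[!te],
                           x[te, , drop = FALSE])
    facc[f] <- mean(pred[te] == labels[te])
  }
  conf <- table(truth = labels, predicted = pred)
  list(accuracy = mean(pred == labels),
       per_class = diag(prop.table(conf, 1)),
       confusion = conf, fold_accuracy = facc)
}
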