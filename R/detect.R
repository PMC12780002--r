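# Noise-robust threshold estimation, spike detection, and peak-aligned
# waveform extraction. The modified threshold excludes supra-threshold
# samples before re-estimating the noise statistics, so large spikes do not
# inflate the detection threshold.

#' Naive amplitude threshold
#'
#' First-pass statistics of a trace: `AVG` (plain mean), `STD` (population
#' standard deviation, divisor n) and `threshold = AVG + factor * STD`.
#' A constant trace yields `STD = 0` and is flagged degenerate. Factors
#' outside the conventional 3-5 range are allowed with a warning.
#'
#' @param trace numeric vector in uV.
#' @param factor threshold multiplier (default 4, midpoint of the 3-5
#'   convention).
#' @return an object of class `mea_threshold` with fields `avg_uv`,
#'   `sd_uv`, `factor`, `threshold_uv`, plus the refined counterparts
#'   (`NA` until [refine_threshold()] fills them) and flags.
#' @export
estimate_threshold <- function(trace, factor = 4) {
  if (length(trace) < 2) stop("estimate_threshold: trace length must be >= 2")
  if (factor < 3 || factor > 5)
    warning("estimate_threshold: factor outside the conventional [3, 5] range")
  avg <- mean(trace)
  sdv <- sqrt(mean((trace - avg)^2))
  structure(list(avg_uv = avg, sd_uv = sdv, factor = factor,
                 threshold_uv = avg + factor * sdv,
                 avg_refined_uv = NA_real_, sd_refined_uv = NA_real_,
                 modified_threshold_uv = NA_real_, n_excluded = NA_integer_,
                 degenerate = sdv == 0, refine_failed = FALSE),
            class = "mea_threshold")
}

#' @export
print.mea_threshold <- function(x, ...) {
  cat(sprintf("<mea_threshold> AVG %.3f, STD %.3f, factor %g -> threshold %.3f uV\n",
              x$avg_uv, x$sd_uv, x$factor, x$threshold_uv))
  if (!is.na(x$modified_threshold_uv))
    cat(sprintf("  refined: AVG' %.3f, STD' %.3f -> modified threshold %.3f uV (%d excluded)\n",
                x$avg_refined_uv, x$sd_refined_uv, x$modified_threshold_uv,
                x$n_excluded))
  invisible(x)
}

#' Refined (modified) amplitude threshold
#'
#' Recomputes the noise statistics over the samples with `|x| <` the naive
#' threshold only, then forms `modified threshold = AVG' + factor * STD'`.
#' By default a single refinement pass is made; `iterate = TRUE` repeats the
#' recomputation until the exclusion set is stable. If every sample would be
#' excluded the naive estimate is returned with `refine_failed = TRUE`.
#'
#' @inheritParams estimate_threshold
#' @param iterate repeat refinement until the kept-sample set is stable.
#' @param max_iter iteration cap when `iterate = TRUE`.
#' @return an `mea_threshold` with the refined fields filled in.
#' @export
refine_threshold <- function(trace, factor = 4, iterate = FALSE, max_iter = 20) {
  est <- estimate_threshold(trace, factor)
  thr <- est$threshold_uv
  n_prev <- -1L
  for (pass in seq_len(if (iterate) max_iter else 1)) {
    keep <- abs(trace) < thr
    if (!any(keep)) {
      est$refine_failed <- TRUE
      warning("refine_threshold: all samples excluded; returning naive estimate")
      return(est)
    }
    kept <- trace[keep]
    avg_r <- mean(kept)
    sd_r <- sqrt(mean((kept - avg_r)^2))
    thr_new <- avg_r + factor * sd_r
    n_ex <- sum(!keep)
    if (iterate && n_ex == n_prev) break
    n_prev <- n_ex
    thr <- thr_new
  }
  est$avg_refined_uv <- avg_r
  est$sd_refined_uv <- sd_r
  est$modified_threshold_uv <- thr_new
  est$n_excluded <- n_ex
  est
}

#' Detect supra-threshold peaks
#'
#' Events are local extrema whose magnitude reaches the modified threshold
#' (falling back to the naive threshold magnitude when refinement is
#' absent), enforced to be separated by at least the refractory period
#' (earlier event wins). With `polarity = "both"` the comparison is
#' `|x| >= threshold`; `"negative"`/`"positive"` restrict to one sign.
#'
#' @param trace numeric vector in uV.
#' @param threshold an `mea_threshold`, or a bare positive number used
#'   directly as the threshold magnitude in uV.
#' @param rate sampling rate (Hz).
#' @param refractory_ms minimum event separation (ms).
#' @param polarity `"both"` (default), `"negative"` or `"positive"`.
#' @param channel channel index recorded in the output table.
#' @return an `mea_events` table (times in seconds, signed amplitudes).
#' @export
detect_peaks <- function(trace, threshold, rate, refractory_ms = 2,
                         polarity = c("both", "negative", "positive"),
                         channel = 1L) {
  polarity <- match.arg(polarity)
  if (!length(trace)) return(event_table())
  thr <- if (inherits(threshold, "mea_threshold")) {
    if (!is.na(threshold$modified_threshold_uv)) threshold$modified_threshold_uv
    else threshold$threshold_uv
  } else as.numeric(threshold)
  if (!is.finite(thr) || thr <= 0)
    stop("detect_peaks: threshold must be a positive finite magnitude")
  a <- switch(polarity, both = abs(trace), negative = -trace,
              positive = trace)
  n <- length(a)
  if (n < 3) return(event_table())
  core <- 2:(n - 1)
  is_peak <- a[core] >= a[core - 1] & a[core] > a[core + 1] & a[core] >= thr
  idx <- core[is_peak]
  if (!length(idx)) return(event_table())
  ref_s <- round(refractory_ms / 1000 * rate)
  keep <- integer(); last <- -Inf
  for (i in idx) {
    if (i - last >= ref_s) { keep <- c(keep, i); last <- i }
  }
  event_table(channel = rep(channel, length(keep)),
              time_s = (keep - 1) / rate,
              code_id = NA_character_,
              amplitude_uv = trace[keep])
}

#' Extract peak-aligned waveform snippets
#'
#' Cuts a window around each event and re-centres it on the extremum of
#' `|x|` within the window (up to `max_recenter` passes), so the sample at
#' `alignment_index` is the waveform's extremum. Events whose window would
#' run past the trace ends are dropped with a warning.
#'
#' @param trace numeric vector in uV.
#' @param events an `mea_events` table (times in seconds).
#' @param rate sampling rate (Hz).
#' @param window_ms total window length (ms); split evenly around the peak.
#'   The default 4 ms covers both neuronal spikes and short tumor
#'   potentials.
#' @param max_recenter re-centring passes (0 disables re-alignment).
#' @return list of `mea_waveform` objects: `samples_uv`,
#'   `alignment_index`, `channel`, `time_s`.
#' @export
extract_waveforms <- function(trace, events, rate, window_ms = 4,
                              max_recenter = 3) {
  half <- round(window_ms / 2 / 1000 * rate)
  n <- length(trace)
  out <- list()
  dropped <- 0L
  for (r in seq_len(nrow(events))) {
    c0 <- round(events$time_s[r] * rate) + 1L
    ok <- TRUE
    for (pass in seq_len(max_recenter + 1)) {
      a <- c0 - half; b <- c0 + half
      if (a < 1 || b > n) { ok <- FALSE; break }
      w <- trace[a:b]
      pk <- which.max(abs(w))
      if (pk == half + 1 || pass > max_recenter) break
      c0 <- a + pk - 1L
    }
    if (!ok) { dropped <- dropped + 1L; next }
    out[[length(out) + 1L]] <-
      structure(list(samples_uv = w, alignment_index = half + 1L,
                     channel = events$channel[r], time_s = (c0 - 1) / rate,
                     code_id = events$code_id[r]),
                class = "mea_waveform")
  }
  if (dropped)
    warning(sprintf("extract_waveforms: dropped %d truncated window(s)", dropped))
  out
}

#' Detect spikes across a whole recording
#'
#' Convenience wrapper: applies the default detection chain
#' ([preprocess_recording()] with `chain = "detect"`), then per-channel
#' threshold refinement and peak detection.
#'
#' @param rec an `mea_recording` or an `mea_filtered` result.
#' @param factor threshold multiplier.
#' @param refractory_ms minimum event separation (ms).
#' @param polarity see [detect_peaks()].
#' @param iterate see [refine_threshold()].
#' @return list: `events` (all channels, `mea_events`), `thresholds`
#'   (per-channel `mea_threshold`), `filtered` (the `mea_filtered` input to
#'   detection).
#' @export
detect_recording <- function(rec, factor = 4, refractory_ms = 2,
                             polarity = "both", iterate = FALSE) {
  filt <- if (inherits(rec, "mea_filtered")) rec
          else preprocess_recording(rec, "detect")
  fs <- filt$sampling_rate_hz
  thr <- list(); evs <- list()
  for (ch in seq_len(nrow(filt$uv))) {
    th <- refine_threshold(filt$uv[ch, ], factor, iterate = iterate)
    thr[[ch]] <- th
    evs[[ch]] <- detect_peaks(filt$uv[ch, ], th, fs, refractory_ms,
                              polarity, channel = ch)
  }
  ev <- do.call(rbind, evs)
  class(ev) <- c("mea_events", "data.frame")
  list(events = ev, thresholds = thr, filtered = filt)
}

#' Score detected events against ground truth
#'
#' Greedy one-to-one matching of detected to true events within a time
#' tolerance, per channel; reports precision, recall and F1 and the
#' false-positive rate per second.
#'
#' @param detected,truth `mea_events` tables.
#' @param tol_ms matching tolerance (ms).
#' @param duration_s recording length, for the false-positive rate.
#' @return list: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `fp_per_s`.
#' @export
score_detection <- function(detected, truth, tol_ms = 1, duration_s = NULL) {
  tol <- tol_ms / 1000
  tp <- 0L
  for (ch in unique(truth$channel)) {
    td <- sort(detected$time_s[detected$channel == ch])
    tt <- truth$time_s[truth$channel == ch]
    used <- logical(length(td))
    for (t0 in tt) {
      j <- findInterval(t0, td)
      cand <- c(j, j + 1L)
      cand <- cand[cand >= 1 & cand <= length(td)]
      cand <- cand[!used[cand] & abs(td[cand] - t0) <= tol]
      if (length(cand)) {
        used[cand[which.min(abs(td[cand] - t0))]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(detected) - tp
  fn <- nrow(truth) - tp
  precision <- if (nrow(detected)) tp / nrow(detected) else NA_real_
  recall <- if (nrow(truth)) tp / nrow(truth) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1,
       fp_per_s = if (is.null(duration_s)) NA_real_ else fp / duration_s)
}
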