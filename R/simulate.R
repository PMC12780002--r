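# Synthetic MEA data with known ground truth: spike templates, recordings,
# event corpora, and migration count tables. Every draw is a pure function
# of (config, seed).

#' Synthesize spike waveform templates
#'
#' Neuronal templates are biphasic (one negative and one positive lobe) with
#' durations drawn from 1.2 +/- 0.3 ms (truncated to one standard
#' deviation). Tumor templates are prolonged multiphasic potentials (>= 3
#' sign-alternating lobes) with durations in 1 to 15.6 ms. Shapes are
#' normalized to unit peak magnitude; the sample of largest magnitude is the
#' declared alignment index.
#'
#' @param n_neuronal,n_tumor number of templates of each kind.
#' @param sampling_rate_hz sampling rate the shapes are rendered at.
#' @param seed integer seed fixing all draws.
#' @param neuronal_duration_ms mean +/- sd of neuronal durations.
#' @param tumor_duration_range_ms admissible tumor durations (ms).
#' @return list of template objects: `kind`, `id`, `duration_ms`,
#'   `polarity`, `shape` (unit peak), `alignment_index`.
#' @export
synth_templates <- function(n_neuronal = 1, n_tumor = 0,
                            sampling_rate_hz = 30000, seed = 1,
                            neuronal_duration_ms = c(1.2, 0.3),
                            tumor_duration_range_ms = c(1, 15.6)) {
  if (neuronal_duration_ms[1] <= 0)
    stop("synth_templates: config error: non-positive neuronal duration")
  if (any(tumor_duration_range_ms <= 0) ||
      tumor_duration_range_ms[1] >= tumor_duration_range_ms[2])
    stop("synth_templates: config error: bad tumor duration range")
  set.seed(seed)
  out <- list()
  k <- 0
  rtrunc_norm <- function(mean, sd, lo, hi) {
    for (i in 1:100) { v <- stats::rnorm(1, mean, sd); if (v >= lo && v <= hi) return(v) }
    mean
  }
  # peak-alignment requires a strict extremum: symmetric lobes can tie two
  # samples at the peak, making alignment ambiguous by one sample
  untie_peak <- function(shape) {
    idx <- which.max(abs(shape))
    ties <- setdiff(which(abs(abs(shape) - abs(shape[idx])) < 1e-12), idx)
    if (length(ties)) shape[ties] <- shape[ties] * 0.995
    shape
  }
  for (i in seq_len(n_neuronal)) {
    dur <- rtrunc_norm(neuronal_duration_ms[1], neuronal_duration_ms[2],
                       neuronal_duration_ms[1] - neuronal_duration_ms[2],
                       neuronal_duration_ms[1] + neuronal_duration_ms[2])
    n <- max(8L, round(dur / 1000 * sampling_rate_hz))
    # biphasic: dominant negative lobe then smaller positive lobe; the
    # lobe-width split and amplitude ratio vary per template
    split <- stats::runif(1, 0.4, 0.6)
    ratio <- stats::runif(1, 0.35, 0.7)
    n1 <- max(3L, round(n * split)); n2 <- max(3L, n - n1)
    shape <- c(-sin(pi * seq_len(n1) / (n1 + 1)),
               ratio * sin(pi * seq_len(n2) / (n2 + 1)))
    shape <- untie_peak(shape / max(abs(shape)))
    k <- k + 1
    out[[k]] <- list(kind = "neuronal", id = sprintf("N%02d", i),
                     duration_ms = dur, polarity = "negative",
                     shape = shape, alignment_index = which.max(abs(shape)))
  }
  for (i in seq_len(n_tumor)) {
    dur <- exp(stats::runif(1, log(tumor_duration_range_ms[1]),
                            log(tumor_duration_range_ms[2])))
    n <- max(16L, round(dur / 1000 * sampling_rate_hz))
    n_lobes <- sample(3:6, 1)
    widths <- stats::runif(n_lobes, 0.5, 1.5)
    widths <- pmax(3L, round(widths / sum(widths) * n))
    amps <- stats::runif(n_lobes, 0.3, 1) * rep_len(c(-1, 1), n_lobes)
    imax <- sample(n_lobes, 1)
    amps[imax] <- sign(amps[imax])  # one lobe carries the unit peak
    shape <- unlist(lapply(seq_len(n_lobes), function(j)
      amps[j] * sin(pi * seq_len(widths[j]) / (widths[j] + 1))))
    shape <- untie_peak(shape / max(abs(shape)))
    k <- k + 1
    out[[k]] <- list(kind = "tumor", id = sprintf("T%02d", i),
                     duration_ms = dur,
                     polarity = if (sign(shape[which.max(abs(shape))]) < 0)
                       "negative" else "positive",
                     shape = shape, alignment_index = which.max(abs(shape)))
  }
  out
}

#' Cell-electrode coupling ratio
#'
#' Fraction of the cellular source voltage that appears at the amplifier
#' input, from the standard point-contact equivalent circuit: the membrane
#' (resistance in parallel with capacitance) in series with the electrode
#' impedance, shunted by the seal resistance of the nanoscale cleft
#' (40-100 nm of culture medium). Evaluated at a reference frequency
#' (default 1 kHz, mid-band of spike energy):
#' `ratio = R_seal / |R_seal + Z_membrane + Z_electrode|`.
#' The ratio is in (0, 1], tends to 1 as `r_seal_ohm -> Inf`, to 0 as
#' `r_seal_ohm -> 0`, and is strictly increasing in `r_seal_ohm`.
#'
#' @param r_seal_ohm seal resistance (ohm).
#' @param membrane_resistance_ohm membrane resistance (ohm).
#' @param membrane_capacitance_f membrane capacitance (farad).
#' @param electrode_impedance_ohm electrode impedance magnitude at the
#'   reference frequency (ohm), treated as resistive.
#' @param freq_hz reference frequency (Hz).
#' @return coupling ratio in (0, 1].
#' @export
coupling_ratio <- function(r_seal_ohm, membrane_resistance_ohm = 1e8,
                           membrane_capacitance_f = 1e-11,
                           electrode_impedance_ohm = 1e6, freq_hz = 1000) {
  if (any(c(r_seal_ohm, membrane_resistance_ohm, membrane_capacitance_f,
            electrode_impedance_ohm, freq_hz) <= 0))
    stop("coupling_ratio: config error: all circuit components must be positive")
  w <- 2 * pi * freq_hz
  zm <- 1 / (1 / membrane_resistance_ohm + 1i * w * membrane_capacitance_f)
  Mod(r_seal_ohm) / Mod(r_seal_ohm + zm + electrode_impedance_ohm)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic recording generator. Defaults are the
#' study conditions the generator emulates: 30 kHz sampling, baseline
#' Gaussian noise of sd 2.4 uV (range about +/-5 uV), neuronal firing at a
#' mean inter-peak interval of 8.5 ms, tumor potentials with
#' interval CV 32%, shared 50 Hz mains pickup plus slow drift as the
#' common-mode component, and 2 ms refractoriness per source.
#'
#' @param seed integer seed.
#' @param duration_s recording length (s).
#' @param n_channels number of electrodes.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param noise_sd_uv baseline noise standard deviation (uV).
#' @param neuron_rate_hz neuronal firing rate per channel (Hz); the default
#'   1/0.0085 targets the 8.5 ms mean inter-peak interval.
#' @param tumor_rate_hz tumor event rate per channel (Hz).
#' @param tumor_interval_cv coefficient of variation of tumor inter-event
#'   intervals (gamma-distributed).
#' @param neuron_amplitude_uv,tumor_amplitude_uv source peak amplitudes (uV).
#' @param amplitude_jitter lognormal sd of per-event amplitude jitter.
#' @param common_mode_amplitude_uv amplitude of the shared 50 Hz sinusoid.
#' @param drift_amplitude_uv amplitude of the shared slow (0.1 Hz) drift.
#' @param refractory_ms enforced minimum separation of events per channel.
#' @param uv_per_count ADC scale (uV per count).
#' @param templates template set from [synth_templates()]; `NULL` draws one
#'   neuronal and (if `tumor_rate_hz > 0`) one tumor template from the seed.
#' @param coupling optional list of [coupling_ratio()] arguments; inserted
#'   event amplitudes are the source amplitude times the coupling ratio.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, duration_s = 10, n_channels = 32,
                       sampling_rate_hz = 30000, noise_sd_uv = 2.4,
                       neuron_rate_hz = 1 / 0.0085, tumor_rate_hz = 0,
                       tumor_interval_cv = 0.32,
                       neuron_amplitude_uv = 40, tumor_amplitude_uv = 80,
                       amplitude_jitter = 0.1,
                       common_mode_amplitude_uv = 8, drift_amplitude_uv = 15,
                       refractory_ms = 2, uv_per_count = 0.195,
                       templates = NULL, coupling = NULL) {
  cfg <- as.list(environment())
  if (cfg$duration_s <= 0 || cfg$n_channels < 1 || cfg$sampling_rate_hz <= 0)
    stop("sim_config: config error: non-positive dimensions")
  if (cfg$neuron_rate_hz < 0 || cfg$tumor_rate_hz < 0)
    stop("sim_config: config error: rates must be >= 0")
  if (cfg$noise_sd_uv < 0) stop("sim_config: config error: negative noise sd")
  class(cfg) <- "sim_config"
  cfg
}

# Poisson event times with an enforced dead time; returns times in seconds.
poisson_refractory <- function(rate_hz, duration_s, refractory_s) {
  if (rate_hz <= 0) return(numeric())
  # choose the exponential part so the realized mean interval is 1/rate
  mean_exp <- 1 / rate_hz - refractory_s
  if (mean_exp <= 0) mean_exp <- 0.1 / rate_hz
  t <- numeric(); cur <- stats::rexp(1, 1 / mean_exp)
  while (cur < duration_s) {
    t <- c(t, cur)
    cur <- cur + refractory_s + stats::rexp(1, 1 / mean_exp)
  }
  t
}

# gamma-interval renewal process with given mean interval and CV
gamma_interval_times <- function(rate_hz, cv, duration_s) {
  if (rate_hz <= 0) return(numeric())
  shape <- 1 / cv^2
  scale <- (1 / rate_hz) / shape
  t <- numeric(); cur <- stats::rgamma(1, shape, scale = scale)
  while (cur < duration_s) {
    t <- c(t, cur)
    cur <- cur + stats::rgamma(1, shape, scale = scale)
  }
  t
}

#' Synthesize a ground-truthed MEA recording
#'
#' Places neuronal and tumor template instances on independent per-channel
#' renewal processes (Poisson with dead time for neurons; gamma intervals at
#' the configured CV for tumor events), sums overlaps linearly, adds i.i.d.
#' Gaussian baseline noise and a shared common-mode component (50 Hz mains +
#' slow drift), applies the coupling attenuation if configured, and
#' quantizes to int16 counts. The returned event table lists every inserted
#' event with its template id, snapped sample time, and signed source peak
#' amplitude in uV.
#'
#' @param config a [sim_config()].
#' @return list with `recording` (an `mea_recording`) and `events`
#'   (ground-truth `mea_events`).
#' @export
synth_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  if (n < 2) stop("synth_recording: duration too short")
  templates <- config$templates
  if (is.null(templates))
    templates <- synth_templates(n_neuronal = 1,
                                 n_tumor = if (config$tumor_rate_hz > 0) 1 else 0,
                                 sampling_rate_hz = fs, seed = config$seed)
  kinds <- vapply(templates, `[[`, "", "kind")
  atten <- if (is.null(config$coupling)) 1 else do.call(coupling_ratio, config$coupling)

  tt <- seq_len(n) / fs
  common <- config$common_mode_amplitude_uv * sin(2 * pi * 50 * tt) +
    config$drift_amplitude_uv * sin(2 * pi * 0.1 * tt)

  ev_ch <- list(); ev_t <- list(); ev_id <- list(); ev_amp <- list()
  counts <- matrix(0L, nrow = config$n_channels, ncol = n)
  for (ch in seq_len(config$n_channels)) {
    v <- stats::rnorm(n, 0, config$noise_sd_uv) + common
    for (kind in c("neuronal", "tumor")) {
      idx_k <- which(kinds == kind)
      if (!length(idx_k)) next
      amp0 <- switch(kind, neuronal = config$neuron_amplitude_uv,
                     tumor = config$tumor_amplitude_uv)
      times <- switch(kind,
        neuronal = poisson_refractory(config$neuron_rate_hz,
                                      config$duration_s,
                                      config$refractory_ms / 1000),
        tumor = gamma_interval_times(config$tumor_rate_hz,
                                     config$tumor_interval_cv,
                                     config$duration_s))
      for (ts in times) {
        tpl <- templates[[if (length(idx_k) == 1) idx_k else sample(idx_k, 1)]]
        s0 <- round(ts * fs)
        a <- s0 - tpl$alignment_index + 1L
        b <- a + length(tpl$shape) - 1L
        if (a < 1 || b > n) next
        amp <- amp0 * atten * exp(stats::rnorm(1, 0, config$amplitude_jitter))
        v[a:b] <- v[a:b] + amp * tpl$shape
        k <- length(ev_ch) + 1L
        ev_ch[[k]] <- ch; ev_t[[k]] <- s0 / fs; ev_id[[k]] <- tpl$id
        ev_amp[[k]] <- amp * tpl$shape[tpl$alignment_index]
      }
    }
    ci <- round(v / config$uv_per_count)
    ci[ci > 32767] <- 32767; ci[ci < -32768] <- -32768
    counts[ch, ] <- as.integer(ci)
  }
  ev_ch <- unlist(ev_ch); ev_t <- unlist(ev_t)
  ev_id <- as.character(unlist(ev_id)); ev_amp <- unlist(ev_amp)
  if (!length(ev_t) &&
      (config$neuron_rate_hz > 0 || config$tumor_rate_hz > 0))
    warning("synth_recording: duration too short to place any event")
  events <- if (length(ev_t)) {
    ord <- order(ev_ch, ev_t)
    event_table(ev_ch[ord], ev_t[ord], ev_id[ord], ev_amp[ord])
  } else event_table()
  list(recording = recording(counts, fs, config$uv_per_count),
       events = events)
}

#' Synthesize an event-sequence corpus
#'
#' Draws i.i.d. code types from `code_distribution` and inter-peak intervals
#' from the given interval model (log-normal by default), split into
#' `n_sequences` sequences. The currency of the sequence generator: ordered
#' (code type, interval ms) pairs.
#'
#' @param code_distribution named numeric vector of code probabilities
#'   (must sum to 1).
#' @param n_events total number of events.
#' @param interval_model list: `dist` ("lognormal" or "gamma"),
#'   `meanlog`/`sdlog` or `mean`/`cv`.
#' @param seed integer seed.
#' @param n_sequences how many sequences to split the corpus into.
#' @return list of data.frames (`code_id`, `interval_ms`) of class
#'   `event_sequence`, with `source = "recorded"` attribute.
#' @export
synth_event_corpus <- function(code_distribution, n_events,
                               interval_model = list(dist = "lognormal",
                                                     meanlog = log(20), sdlog = 0.5),
                               seed = 1, n_sequences = 1) {
  if (!length(code_distribution))
    stop("synth_event_corpus: config error: empty code alphabet")
  if (abs(sum(code_distribution) - 1) > 1e-8)
    stop("synth_event_corpus: config error: distribution must sum to 1")
  if (is.null(names(code_distribution)))
    names(code_distribution) <- sprintf("C%03d", seq_along(code_distribution))
  set.seed(seed)
  if (n_events == 0) return(list())
  codes <- sample(names(code_distribution), n_events, replace = TRUE,
                  prob = code_distribution)
  iv <- switch(interval_model$dist,
    lognormal = stats::rlnorm(n_events, interval_model$meanlog, interval_model$sdlog),
    gamma = {
      shape <- 1 / interval_model$cv^2
      stats::rgamma(n_events, shape, scale = interval_model$mean / shape)
    },
    stop("synth_event_corpus: config error: unknown interval model"))
  bounds <- floor(seq(0, n_events, length.out = n_sequences + 1))
  lapply(seq_len(n_sequences), function(i) {
    r <- (bounds[i] + 1):bounds[i + 1]
    s <- data.frame(code_id = codes[r], interval_ms = iv[r],
                    stringsAsFactors = FALSE)
    attr(s, "source") <- "recorded"
    class(s) <- c("event_sequence", "data.frame")
    s
  })
}

#' Synthesize a migration count table
#'
#' Emulates a 7-day invasion experiment on a linear electrode channel. A
#' logistic front advances along the array (fast and saturating by day 4
#' for the `hyper` profile; slow for `normal`); each day's counts are a
#' sample of `n_cells` positions from a discretized Gaussian centred on the
#' front. Cells share one uniform draw across days (common random numbers),
#' so each simulated cell's position is non-decreasing over days and the
#' population front never artificially retreats, while each day's marginal
#' count distribution is exactly the multinomial around the front.
#'
#' @param profile `"normal"` or `"hyper"`.
#' @param n_days number of days (rows).
#' @param n_electrodes number of electrodes (columns).
#' @param seed integer seed.
#' @param n_cells number of simulated cells.
#' @param pitch_um electrode pitch (um).
#' @return an `mea_counts` table (see [count_table()]).
#' @export
synth_migration <- function(profile = c("normal", "hyper"), n_days = 7,
                            n_electrodes = 32, seed = 1, n_cells = 2000,
                            pitch_um = 200) {
  profile <- match.arg(profile)
  if (n_days < 1) stop("synth_migration: config error: n_days must be >= 1")
  set.seed(seed)
  front <- function(day) {
    L <- switch(profile,
                hyper = stats::plogis(2.0 * (day - 1.5)),
                normal = stats::plogis(0.5 * (day - 5.5)))
    1 + (n_electrodes - 1) * L
  }
  u <- stats::runif(n_cells)
  counts <- matrix(0L, nrow = n_days, ncol = n_electrodes)
  for (d in seq_len(n_days)) {
    w <- exp(-((seq_len(n_electrodes) - front(d))^2) / (2 * 2^2))
    cdf <- cumsum(w) / sum(w)
    pos <- findInterval(u, cdf) + 1L  # inverse-CDF with shared u per cell
    counts[d, ] <- tabulate(pos, nbins = n_electrodes)
  }
  count_table(counts, days = sprintf("day%d", seq_len(n_days)),
              pitch_um = pitch_um, condition = profile)
}
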