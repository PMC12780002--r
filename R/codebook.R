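# Unsupervised template-library classification of peak-aligned waveforms
# into recurring "neural code" types, and code-frequency profiling.

new_code_library <- function(codes = list(), tolerance = 0.30,
                             consistency_min = 0.90) {
  if (tolerance <= 0 || tolerance >= 1)
    stop("code_library: tolerance must be in (0, 1)")
  if (consistency_min <= 0 || consistency_min > 1)
    stop("code_library: consistency_min must be in (0, 1]")
  ids <- vapply(codes, `[[`, "", "code_id")
  if (anyDuplicated(ids)) stop("code_library: duplicate code ids")
  structure(list(codes = codes, tolerance = tolerance,
                 consistency_min = consistency_min),
            class = "code_library")
}

#' @export
print.code_library <- function(x, ...) {
  cat(sprintf("<code_library> %d code(s), tolerance %.2f, consistency >= %.2f\n",
              length(x$codes), x$tolerance, x$consistency_min))
  invisible(x)
}

# standardize a waveform vector to the template length, keeping the
# alignment sample fixed: center-crop or zero-pad on both sides
conform_waveform <- function(w, align, len, align_to) {
  out <- numeric(len)
  src <- seq_along(w) - align          # offsets relative to peak
  dst <- src + align_to
  ok <- dst >= 1 & dst <= len
  out[dst[ok]] <- w[ok]
  out
}

#' Per-sample label consistency between a waveform and a template
#'
#' Digit-by-digit comparison outward from the peak-alignment point: the
#' fraction of sample positions whose deviation from the template, relative
#' to the template's peak magnitude, is within `tolerance` (default 30%).
#' Both inputs must be peak-aligned and of equal length.
#'
#' @param waveform,template numeric vectors (uV), peak-aligned, equal
#'   length.
#' @param tolerance relative deviation threshold (default 0.30).
#' @param eps guard for near-zero template peaks.
#' @return fraction in \[0, 1\].
#' @export
sample_consistency <- function(waveform, template, tolerance = 0.30,
                               eps = 1e-9) {
  if (length(waveform) != length(template))
    stop("sample_consistency: length mismatch")
  peak <- max(abs(template), eps)
  mean(abs(waveform - template) / peak <= tolerance)
}

#' Classify one waveform against a code library
#'
#' Scans templates in library order and assigns the waveform to the first
#' whose sample consistency reaches `consistency_min` (first-match-wins;
#' `best_match = TRUE` instead assigns to the highest-consistency match).
#' An unmatched waveform founds a new code whose template is the waveform
#' itself. Waveforms of a different length than the library's templates are
#' center-cropped / zero-padded with a warning.
#'
#' @param waveform an `mea_waveform` or numeric vector (then assumed
#'   peak-aligned at its extremum).
#' @param library a `code_library`.
#' @param best_match assign to the maximum-consistency template instead of
#'   the first match.
#' @return list: `code_id`, `library` (updated), `consistency` (of the
#'   match; 1 for a newly founded code), `is_new`.
#' @export
classify_waveform <- function(waveform, library, best_match = FALSE) {
  w <- if (inherits(waveform, "mea_waveform")) waveform$samples_uv else waveform
  align <- if (inherits(waveform, "mea_waveform")) waveform$alignment_index
           else which.max(abs(w))
  if (length(library$codes)) {
    len <- length(library$codes[[1]]$template_uv)
    align_to <- library$codes[[1]]$alignment_index
    if (length(w) != len) {
      warning("classify_waveform: conforming waveform length ", length(w),
              " to library length ", len)
      w <- conform_waveform(w, align, len, align_to)
      align <- align_to
    }
    cons <- vapply(library$codes, function(cd)
      sample_consistency(w, cd$template_uv, library$tolerance), 0)
    hit <- if (best_match) {
      h <- which.max(cons)
      if (cons[h] >= library$consistency_min) h else 0L
    } else {
      h <- which(cons >= library$consistency_min)
      if (length(h)) h[1] else 0L
    }
    if (hit > 0) {
      cd <- library$codes[[hit]]
      cd$n_members <- cd$n_members + 1L
      cd$envelope_min <- pmin(cd$envelope_min, w)
      cd$envelope_max <- pmax(cd$envelope_max, w)
      library$codes[[hit]] <- cd
      return(list(code_id = cd$code_id, library = library,
                  consistency = cons[hit], is_new = FALSE))
    }
  }
  id <- sprintf("C%03d", length(library$codes) + 1L)
  library$codes[[length(library$codes) + 1L]] <-
    list(code_id = id, template_uv = w, alignment_index = align,
         n_members = 1L, envelope_min = w, envelope_max = w)
  list(code_id = id, library = library, consistency = 1, is_new = TRUE)
}

#' Build a code library from a waveform stream
#'
#' Single sequential pass in input order: each waveform is classified
#' against the growing library ([classify_waveform()]); unmatched waveforms
#' found new codes. The first member waveform of a code remains its
#' template; the envelope tracks the per-sample member range.
#'
#' @param waveforms list of `mea_waveform` objects or numeric vectors.
#' @param tolerance per-sample relative deviation threshold.
#' @param consistency_min minimum fraction of in-tolerance samples.
#' @param best_match see [classify_waveform()].
#' @return list: `library` (a `code_library`), `assignments` (character
#'   vector of code ids, one per input).
#' @export
build_codebook <- function(waveforms, tolerance = 0.30,
                           consistency_min = 0.90, best_match = FALSE) {
  lib <- new_code_library(tolerance = tolerance,
                          consistency_min = consistency_min)
  assignments <- character(length(waveforms))
  for (i in seq_along(waveforms)) {
    res <- classify_waveform(waveforms[[i]], lib, best_match = best_match)
    lib <- res$library
    assignments[i] <- res$code_id
  }
  list(library = lib, assignments = assignments)
}

#' Code-frequency profile of a recording
#'
#' Relative frequency of each code among the assignments, with an optional
#' top-k selection (ties broken by code id order).
#'
#' @param assignments character vector of code ids.
#' @param top_k keep only the `top_k` most frequent codes in the `top`
#'   field (all codes remain in `frequency`); `NULL` keeps all.
#' @return object of class `code_profile`: `frequency` (named, sums to 1),
#'   `counts`, `total_events`, `top` (code ids).
#' @export
code_profile <- function(assignments, top_k = NULL) {
  if (!length(assignments)) stop("code_profile: empty assignments")
  counts <- table(assignments)
  counts <- counts[order(names(counts))]
  freq <- as.numeric(counts) / sum(counts)
  names(freq) <- names(counts)
  ord <- order(-freq, names(freq))
  if (is.null(top_k)) top_k <- length(freq)
  if (top_k > length(freq)) {
    warning("code_profile: top_k exceeds number of codes; returning all")
    top_k <- length(freq)
  }
  structure(list(frequency = freq, counts = as.integer(counts),
                 total_events = length(assignments),
                 top = names(freq)[ord][seq_len(top_k)]),
            class = "code_profile")
}

#' Compare two code-frequency profiles
#'
#' Aligns both profiles on the union of their code alphabets (absent codes
#' count 0), reports per-code frequency deltas (summing to 0) and a
#' chi-square homogeneity test on the count table.
#'
#' @param profile_a,profile_b `code_profile` objects.
#' @return list: `delta` (named, a - b), `chi_sq`, `df`, `p_value`.
#' @export
compare_profiles <- function(profile_a, profile_b) {
  if (profile_a$total_events == 0 || profile_b$total_events == 0)
    stop("compare_profiles: zero-total profile")
  codes <- sort(union(names(profile_a$frequency), names(profile_b$frequency)))
  ca <- stats::setNames(rep(0L, length(codes)), codes)
  cb <- ca
  ca[names(profile_a$frequency)] <- profile_a$counts
  cb[names(profile_b$frequency)] <- profile_b$counts
  fa <- ca / sum(ca); fb <- cb / sum(cb)
  keep <- ca + cb > 0
  if (identical(as.integer(ca), as.integer(cb))) {
    chi <- 0; df <- sum(keep) - 1; p <- 1
  } else {
    tst <- suppressWarnings(stats::chisq.test(rbind(ca[keep], cb[keep])))
    chi <- unname(tst$statistic); df <- unname(tst$parameter)
    p <- unname(tst$p.value)
  }
  list(delta = fa - fb, chi_sq = chi, df = df, p_value = p)
}

#' Build a code library directly from simulator templates
#'
#' Renders each template at its nominal amplitude into a fixed-length,
#' peak-aligned snippet matching the detection window, and founds one code
#' per template. Used to close the render -> detect -> classify loop on
#' synthetic data.
#'
#' @param templates list from [synth_templates()].
#' @param rate sampling rate (Hz).
#' @param window_ms extraction window (must cover the template span).
#' @param amplitudes_uv numeric vector of peak amplitudes (recycled).
#' @param tolerance,consistency_min library parameters.
#' @return a `code_library` whose code ids are the template ids.
#' @export
library_from_templates <- function(templates, rate, window_ms = 4,
                                   amplitudes_uv = 40, tolerance = 0.30,
                                   consistency_min = 0.90) {
  half <- round(window_ms / 2 / 1000 * rate)
  len <- 2L * half + 1L
  amplitudes_uv <- rep_len(amplitudes_uv, length(templates))
  codes <- lapply(seq_along(templates), function(i) {
    tpl <- templates[[i]]
    w <- conform_waveform(amplitudes_uv[i] * tpl$shape, tpl$alignment_index,
                          len, half + 1L)
    list(code_id = tpl$id, template_uv = w, alignment_index = half + 1L,
         n_members = 1L, envelope_min = w, envelope_max = w)
  })
  new_code_library(codes, tolerance = tolerance,
                   consistency_min = consistency_min)
}

#' Plant well-separated code templates for recovery experiments
#'
#' Draws synthetic spike templates ([synth_templates()]) and keeps only
#' those whose sample consistency against every already-accepted template
#' is below `max_mutual_consistency`, so the planted classes are genuinely
#' distinct under the classification metric. This is the standard setup for
#' clustering-recovery experiments: ground-truth classes must be separated
#' for recovery to be well-defined.
#'
#' @param n number of templates to plant.
#' @param rate sampling rate (Hz).
#' @param window_ms snippet window the templates are rendered into.
#' @param amplitude_uv rendered peak amplitude.
#' @param seed integer seed.
#' @param max_mutual_consistency pairwise separation bound (default 0.8,
#'   safely below the 0.9 grouping threshold).
#' @param tolerance consistency tolerance used for the separation check.
#' @return list of `n` fixed-length, peak-aligned numeric templates with
#'   names `P01..Pnn`.
#' @export
plant_code_templates <- function(n, rate = 30000, window_ms = 4,
                                 amplitude_uv = 40, seed = 1,
                                 max_mutual_consistency = 0.8,
                                 tolerance = 0.30) {
  half <- round(window_ms / 2 / 1000 * rate)
  len <- 2L * half + 1L
  accepted <- list()
  s <- seed
  while (length(accepted) < n && s < seed + 200 * n) {
    cand <- synth_templates(n_neuronal = 1, n_tumor = 1,
                            sampling_rate_hz = rate, seed = s)
    s <- s + 1
    for (tpl in cand) {
      if (length(accepted) >= n) break
      w <- conform_waveform(amplitude_uv * tpl$shape, tpl$alignment_index,
                            len, half + 1L)
      ok <- all(vapply(accepted, function(a)
        sample_consistency(w, a, tolerance) < max_mutual_consistency, TRUE))
      if (ok) accepted[[length(accepted) + 1L]] <- w
    }
  }
  if (length(accepted) < n)
    stop("plant_code_templates: could not find enough separated templates")
  names(accepted) <- sprintf("P%02d", seq_len(n))
  accepted
}
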