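# Shared fixtures and independent oracles used across test files.

# adjusted Rand index between two labelings (independent implementation)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  ex <- si * sj / choose(n, 2)
  (sij - ex) / ((si + sj) / 2 - ex)
}

# brute-force threshold refinement oracle: explicit loops, no shared code
# with the package implementation
brute_refine <- function(trace, factor) {
  n <- length(trace)
  avg <- 0
  for (v in trace) avg <- avg + v
  avg <- avg / n
  ss <- 0
  for (v in trace) ss <- ss + (v - avg)^2
  sdv <- sqrt(ss / n)
  thr <- avg + factor * sdv
  kept <- c()
  for (v in trace) if (abs(v) < thr) kept <- c(kept, v)
  if (!length(kept)) return(NULL)
  avg2 <- 0
  for (v in kept) avg2 <- avg2 + v
  avg2 <- avg2 / length(kept)
  ss2 <- 0
  for (v in kept) ss2 <- ss2 + (v - avg2)^2
  sd2 <- sqrt(ss2 / length(kept))
  list(avg = avg, sd = sdv, threshold = thr,
       avg_refined = avg2, sd_refined = sd2,
       modified = avg2 + factor * sd2, n_excluded = n - length(kept))
}

# build a code_library directly from named fixed-length templates
lib_from_planted <- function(tp, tolerance = 0.30, consistency_min = 0.90) {
  align <- (length(tp[[1]]) + 1L) / 2L
  codes <- lapply(seq_along(tp), function(i)
    list(code_id = names(tp)[i], template_uv = tp[[i]],
         alignment_index = as.integer(align), n_members = 1L,
         envelope_min = tp[[i]], envelope_max = tp[[i]]))
  neurocode:::new_code_library(codes, tolerance = tolerance,
                               consistency_min = consistency_min)
}

# noisy instances of planted templates with ground-truth labels
planted_waveforms <- function(tp, n_per, jitter = 0.05, noise_sd = 0,
                              seed = 1) {
  set.seed(seed)
  wfs <- list(); truth <- character()
  for (i in seq_len(n_per * length(tp))) {
    k <- ((i - 1) %% length(tp)) + 1
    w <- tp[[k]] * exp(rnorm(1, 0, jitter))
    if (noise_sd > 0) w <- w + rnorm(length(w), 0, noise_sd)
    wfs[[i]] <- w
    truth[i] <- names(tp)[k]
  }
  list(waveforms = wfs, truth = truth)
}
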