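# Population-level invasion quantification along a linear electrode
# channel: the Cell Migration Center (CMC), its daily trajectory,
# normalized invasion heatmaps, and condition comparison.

#' Construct a per-day per-electrode cell-count table
#'
#' @param counts day x electrode matrix of non-negative integers (cells
#'   counted near each electrode, nearest-electrode binning by half-pitch
#'   windows).
#' @param days optional day labels (default `day1, day2, ...`).
#' @param pitch_um electrode center-to-center distance (um).
#' @param condition optional condition label (e.g. `"normal"`, `"hyper"`).
#' @return object of class `mea_counts`.
#' @export
count_table <- function(counts, days = NULL, pitch_um = 200,
                        condition = NA_character_) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("count_table: counts must be non-negative")
  if (any(counts != round(counts)))
    stop("count_table: counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(days)) days <- sprintf("day%d", seq_len(nrow(counts)))
  if (length(days) != nrow(counts))
    stop("count_table: day labels do not match rows")
  if (pitch_um <= 0) stop("count_table: pitch must be positive")
  structure(list(counts = counts, days = as.character(days),
                 pitch_um = pitch_um, n_electrodes = ncol(counts),
                 condition = condition),
            class = "mea_counts")
}

#' @export
print.mea_counts <- function(x, ...) {
  cat(sprintf("<mea_counts> %d day(s) x %d electrode(s), pitch %g um%s\n",
              nrow(x$counts), x$n_electrodes, x$pitch_um,
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  invisible(x)
}

#' Cell Migration Center of one day's counts
#'
#' The count-weighted mean electrode position:
#' `CMC = sum(i * CN_i * d) / sum(CN_i)`, where `i` is the 1-based
#' electrode serial number, `CN_i` the cell count near electrode `i` and
#' `d` the pitch. Cells farther along the channel carry larger weight, so
#' CMC tracks the population invasion front. It is bounded by
#' `d <= CMC <= n * d`, shifts by exactly `d` when every cell moves one
#' electrode forward, and is invariant to scaling all counts. An all-zero
#' row has no defined center and returns `NA` (flagged), never 0.
#'
#' @param counts_row non-negative counts, one per electrode.
#' @param pitch_um electrode pitch `d` (um).
#' @return CMC in um, or `NA_real_` if the row is all zero.
#' @export
compute_cmc <- function(counts_row, pitch_um = 200) {
  if (any(counts_row < 0)) stop("compute_cmc: negative count")
  tot <- sum(counts_row)
  if (tot == 0) return(NA_real_)
  sum(seq_along(counts_row) * counts_row * pitch_um) / tot
}

#' CMC trajectory of a count table
#'
#' One CMC per day; all-zero days are `NA` (excluded from trend
#' statistics downstream, never coerced to 0).
#'
#' @param table an `mea_counts`.
#' @return object of class `migration_result`: `days`, `cmc_um`,
#'   `normalized_front` (CMC / (n * d)), `pitch_um`, `condition`.
#' @export
cmc_timeseries <- function(table) {
  stopifnot(inherits(table, "mea_counts"))
  if (!nrow(table$counts)) stop("cmc_timeseries: empty table")
  cmc <- apply(table$counts, 1, compute_cmc, pitch_um = table$pitch_um)
  structure(list(days = table$days, cmc_um = unname(cmc),
                 normalized_front = unname(cmc) /
                   (table$n_electrodes * table$pitch_um),
                 pitch_um = table$pitch_um, condition = table$condition),
            class = "migration_result")
}

#' @export
print.migration_result <- function(x, ...) {
  cat(sprintf("<migration_result>%s\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]")))
  print(data.frame(day = x$days, cmc_um = round(x$cmc_um, 1)))
  invisible(x)
}

#' Normalized invasion heatmap matrix
#'
#' Per-day max-normalization of the count table to \[0, 1\]; all-zero days
#' stay zero. Row scaling by any positive constant leaves the heatmap
#' unchanged.
#'
#' @param table an `mea_counts`.
#' @return day x electrode numeric matrix in \[0, 1\].
#' @export
invasion_heatmap <- function(table) {
  stopifnot(inherits(table, "mea_counts"))
  t(apply(table$counts, 1, function(r) {
    m <- max(r)
    if (m == 0) as.numeric(r) else as.numeric(r) / m
  }))
}

#' Compare CMC trajectories between two conditions
#'
#' Per-day mean +/- SD for each condition, per-day differences, and a
#' paired (default) or Welch t-test across replicate series; a
#' Kolmogorov-Smirnov normality check of the per-day differences is logged
#' alongside. Requires >= 2 replicates per condition and matching day
#' grids.
#'
#' @param results_a,results_b lists of `migration_result` replicates.
#' @param paired paired t-test (replicates matched by position).
#' @return data.frame with per-day `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `diff`, `t`, `p_value`, `normality_p`.
#' @export
compare_conditions <- function(results_a, results_b, paired = TRUE) {
  if (inherits(results_a, "migration_result")) results_a <- list(results_a)
  if (inherits(results_b, "migration_result")) results_b <- list(results_b)
  if (length(results_a) < 2 || length(results_b) < 2)
    stop("compare_conditions: need >= 2 replicate series per condition")
  days <- results_a[[1]]$days
  all_same <- all(vapply(c(results_a, results_b),
                         function(r) identical(r$days, days), TRUE))
  if (!all_same) stop("compare_conditions: mismatched day grids")
  ma <- do.call(rbind, lapply(results_a, `[[`, "cmc_um"))
  mb <- do.call(rbind, lapply(results_b, `[[`, "cmc_um"))
  if (paired && nrow(ma) != nrow(mb))
    stop("compare_conditions: paired test needs equal replicate counts")
  out <- lapply(seq_along(days), function(d) {
    a <- ma[, d]; b <- mb[, d]
    tt <- tryCatch(stats::t.test(a, b, paired = paired),
                   error = function(e) NULL)
    dif <- if (paired) a - b else NULL
    np <- if (paired && stats::sd(dif) > 0)
      suppressWarnings(stats::ks.test(scale(dif), "pnorm")$p.value)
    else NA_real_
    tstat <- if (!is.null(tt) && is.finite(tt$statistic)) unname(tt$statistic)
             else if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    pval <- if (!is.null(tt) && is.finite(tt$p.value)) tt$p.value
            else if (mean(a) == mean(b)) 1 else 0
    data.frame(day = days[d], mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               diff = mean(a) - mean(b),
               t = tstat, p_value = pval, normality_p = np)
  })
  do.call(rbind, out)
}
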