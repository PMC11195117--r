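#' Activity-pattern correlation between two trials
#'
#' Pearson correlation between the boutons-by-time activity patterns of two
#' trials of a `trial_tensor`, flattened over boutons and time.
#'
#' @param tensor a `trial_tensor`.
#' @param trial_i,trial_j trial indices.
#' @return Pearson r.
#' @export
activity_pattern_correlation <- function(tensor, trial_i, trial_j) {
  a <- as.vector(tensor$activity[, trial_i, ])
  b <- as.vector(tensor$activity[, trial_j, ])
  stop_if_not(stats::sd(a) > 0 && stats::sd(b) > 0,
              "correlation undefined for a zero-variance pattern")
  stats::cor(a, b)
}

#' Bin trial-pair statistics by movement-trajectory correlation
#'
#' Averages a per-pair statistic within the six movement-correlation bins
#' -0.2..0, 0..0.2, 0.2..0.4, 0.4..0.6, 0.6..0.8 and 0.8..1. Bins are
#' half-open `[lo, hi)` except the last, which is closed at 1. Pairs with
#' movement correlation below -0.2 are excluded.
#'
#' @param movement_r per-pair movement-trajectory correlations.
#' @param stat per-pair statistic to average (same length).
#' @param breaks bin edges (default `seq(-0.2, 1, 0.2)`).
#' @return data frame: bin_lo, bin_hi, mean, n (NA mean for empty bins).
#' @export
bin_by_movement_correlation <- function(movement_r, stat,
                                        breaks = seq(-0.2, 1, 0.2)) {
  stop_if_not(length(movement_r) == length(stat),
              "movement_r and stat must have equal length")
  n_bins <- length(breaks) - 1L
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  idx <- rep(NA_integer_, length(movement_r))
  eps <- 1e-9  # guards exact edge values against floating-point drift
  for (k in seq_len(n_bins)) {
    in_bin <- movement_r >= lo[k] - eps &
      (movement_r < hi[k] - eps |
         (k == n_bins & movement_r <= hi[k] + eps))
    idx[in_bin] <- k
  }
  data.frame(
    bin_lo = lo, bin_hi = hi,
    mean = vapply(seq_len(n_bins), function(k) {
      v <- stat[!is.na(idx) & idx == k]
      if (length(v)) mean(v) else NA_real_
    }, 0),
    n = vapply(seq_len(n_bins), function(k) sum(idx == k, na.rm = TRUE), 0L)
  )
}

#' Number of responsive boutons activated in a trial
#'
#' A responsive bouton counts as activated when it has at least one detected
#' calcium event inside the outcome-association window around the movement
#' onset (330 ms before to 670 ms after, by default).
#'
#' @param events event table with `bouton_id` and `time_s` columns.
#' @param onset trial movement onset, s.
#' @param responsive_set bouton ids in the responsive ensemble.
#' @param window window (s) relative to onset, default c(-0.33, 0.67).
#' @return integer count.
#' @export
activated_count <- function(events, onset, responsive_set,
                            window = c(-0.33, 0.67)) {
  if (!length(responsive_set) || !nrow(events)) return(0L)
  hit <- events$bouton_id %in% responsive_set &
    events$time_s >= onset + window[1] & events$time_s <= onset + window[2]
  length(unique(events$bouton_id[hit]))
}

#' Activated-ensemble difference for a trial pair
#'
#' `|a - b| / (0.5 * (a + b))`: the difference in activated-ensemble size
#' normalized by the pair's mean, bounded in 0..2.
#'
#' @param a,b activated counts in the two trials.
#' @return dimensionless fraction in 0..2.
#' @export
ensemble_difference <- function(a, b) {
  stop_if_not(a >= 0 && b >= 0, "counts must be non-negative")
  stop_if_not(a + b > 0, "ensemble difference undefined when both counts are 0")
  abs(a - b) / (0.5 * (a + b))
}
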