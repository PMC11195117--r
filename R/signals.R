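#' dF/F with a sliding-percentile baseline
#'
#' For each frame the baseline F0 is the 30th percentile (linear
#' interpolation between order statistics) of the raw fluorescence within a
#' centered 30-s sliding window, truncated at the trace edges; dF/F is
#' `(F - F0) / F0`. The ratio makes the result exactly invariant under
#' positive rescaling of the raw trace.
#'
#' @param raw positive numeric trace, or a boutons-by-frames matrix.
#' @param frame_rate Hz.
#' @param window sliding-window length, s (default 30).
#' @param percentile baseline percentile in 0..100 (default 30).
#' @return dF/F trace (or matrix) of the same shape as `raw`.
#' @export
compute_dff <- function(raw, frame_rate, window = 30, percentile = 30) {
  if (is.matrix(raw)) {
    out <- t(apply(raw, 1, compute_dff, frame_rate = frame_rate,
                   window = window, percentile = percentile))
    dimnames(out) <- dimnames(raw)
    return(out)
  }
  stop_if_not(all(is.finite(raw)) && all(raw > 0),
              "raw fluorescence must be positive and finite")
  stop_if_not(window * frame_rate >= 2,
              "window must span at least 2 frames")
  half <- floor(window * frame_rate / 2)
  f0 <- .rolling_quantile_cpp(raw, as.integer(half), percentile / 100)
  if (any(f0 <= 0)) stop("degenerate baseline: nonpositive F0", call. = FALSE)
  (raw - f0) / f0
}

#' z-score a trace over its full segment
#'
#' @param x numeric trace (typically dF/F of one continuous imaged segment).
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zscore_trace <- function(x) {
  s <- stats::sd(x)
  stop_if_not(is.finite(s) && s > 0, "z-score undefined for zero variance")
  (x - mean(x)) / s
}

# local maxima: strictly greater than both neighbors; a plateau yields its
# first sample. Endpoints are never peaks.
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  dx <- diff(x)
  # position of last nonzero slope before each point handles plateaus:
  # rising into the plateau and falling after it counts once, at entry.
  rise <- dx > 0
  fall <- dx < 0
  peaks <- integer(0)
  state <- 0L  # 1 after a rise
  start_plateau <- 0L
  for (i in seq_len(n - 1)) {
    if (rise[i]) {
      state <- 1L
      start_plateau <- i + 1L
    } else if (fall[i]) {
      if (state == 1L) peaks <- c(peaks, start_plateau)
      state <- 0L
    }
  }
  peaks
}

#' Detect calcium events with a dual criterion
#'
#' Local maxima of the dF/F trace are kept as events when both (1) the
#' z-scored dF/F at the peak exceeds `z_thresh` standard deviations and
#' (2) the raw dF/F at the peak exceeds `raw_thresh` (an 8% fluorescence
#' change by default). Peaks closer than `min_sep` frames are reduced to the
#' largest peak.
#'
#' @param dff dF/F trace of one segment.
#' @param z optional z-scored trace; computed with [zscore_trace()] if NULL.
#' @param z_thresh z-score criterion (default 1).
#' @param raw_thresh dF/F criterion (default 0.08).
#' @param frame_rate Hz, used to convert peak frames to seconds.
#' @param min_sep minimum peak separation in frames (default 3).
#' @return data frame (class `event_train`): time_s, amplitude (dF/F), z.
#' @export
detect_events <- function(dff, z = NULL, z_thresh = 1, raw_thresh = 0.08,
                          frame_rate, min_sep = 3) {
  if (is.null(z)) z <- zscore_trace(dff)
  stop_if_not(length(dff) == length(z), "dff and z must have equal length")
  idx <- find_local_maxima(dff)
  idx <- idx[z[idx] > z_thresh & dff[idx] > raw_thresh]
  if (length(idx) > 1 && min_sep > 1) {
    # keep the larger of any peaks closer than min_sep frames
    ord <- idx[order(dff[idx], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord)
      if (!any(abs(kept - i) < min_sep)) kept <- c(kept, i)
    idx <- sort(kept)
  }
  out <- data.frame(time_s = (idx - 1) / frame_rate,
                    amplitude = dff[idx], z = z[idx])
  class(out) <- c("event_train", "data.frame")
  out
}

#' Detect events for every bouton of a fluorescence set
#'
#' @param fluor a `fluor_set`.
#' @param ... passed to [detect_events()].
#' @return data frame with bouton_id, axon_id, time_s, amplitude, z.
#' @export
detect_events_all <- function(fluor, ...) {
  dff <- compute_dff(fluor$raw, fluor$frame_rate)
  res <- lapply(seq_len(nrow(dff)), function(b) {
    ev <- detect_events(dff[b, ], frame_rate = fluor$frame_rate, ...)
    if (!nrow(ev)) return(NULL)
    cbind(bouton_id = fluor$bouton_ids[b], axon_id = fluor$axon_of[b],
          as.data.frame(ev))
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(bouton_id = integer(0), axon_id = integer(0),
                      time_s = numeric(0), amplitude = numeric(0),
                      z = numeric(0))
  rownames(out) <- NULL
  out
}
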