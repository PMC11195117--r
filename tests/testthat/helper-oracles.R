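# Independent oracles and fixture builders used across the suite.

# type-7 quantile by explicit sort and interpolation between order statistics
quantile_sort_oracle <- function(w, p) {
  s <- sort(w)
  n <- length(s)
  if (n == 1) return(s)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo >= n - 1) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# sliding-percentile baseline by brute force (centered, edge-truncated)
dff_oracle <- function(raw, frame_rate, window = 30, percentile = 30) {
  half <- floor(window * frame_rate / 2)
  n <- length(raw)
  f0 <- vapply(seq_len(n), function(i)
    quantile_sort_oracle(raw[max(1, i - half):min(n, i + half)],
                         percentile / 100), 0)
  (raw - f0) / f0
}

# maximum-cardinality bipartite matching between two trains by exhaustive
# recursion (events pairable iff |ti - tj| <= tol); returns the count
max_matching_oracle <- function(ti, tj, tol) {
  rec <- function(i, used_j) {
    if (i > length(ti)) return(0L)
    best <- rec(i + 1L, used_j)  # leave event i unmatched
    cand <- which(!used_j & abs(tj - ti[i]) <= tol)
    for (j in cand) {
      used_j[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used_j))
      used_j[j] <- FALSE
    }
    best
  }
  rec(1L, rep(FALSE, length(tj)))
}

# random sorted event train with minimum spacing
random_train <- function(n, duration, min_gap) {
  if (n == 0) return(numeric(0))
  t <- sort(runif(n, 0, duration))
  keep <- rep(TRUE, n)
  last <- t[1]
  for (i in seq_len(n)[-1]) {
    if (t[i] - last < min_gap) keep[i] <- FALSE else last <- t[i]
  }
  t[keep]
}

# lever session built directly from square pulses (for bout-detection tests)
make_pulse_session <- function(onsets, durations, peaks, sr = 100,
                               duration = NULL, cue_onsets = numeric(0),
                               task_period = 10, push_threshold = 1.5,
                               noise_sd = 0) {
  duration <- duration %||% (max(onsets + durations) + 2)
  n <- round(duration * sr)
  tgrid <- (seq_len(n) - 1) / sr
  pos <- rnorm(n, 0, noise_sd)
  for (k in seq_along(onsets)) {
    idx <- tgrid >= onsets[k] & tgrid < onsets[k] + durations[k]
    pos[idx] <- pos[idx] + peaks[k]
  }
  structure(list(positions = pos, sample_rate = sr, cue_onsets = cue_onsets,
                 task_period = task_period, push_threshold = push_threshold,
                 iti_duration = 4, duration = duration,
                 truth = data.frame()),
            class = "lever_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small trial tensor built from an explicit boutons x trials x time array
make_tensor <- function(activity, labels, frame_rate = 15, t0 = -1) {
  structure(list(
    activity = activity,
    time = t0 + (seq_len(dim(activity)[3]) - 1) / frame_rate,
    labels = labels, onsets = seq_along(labels),
    frame_rate = frame_rate, dropped = integer(0)
  ), class = "trial_tensor")
}
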