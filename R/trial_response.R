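#' Align bouton activity to movement onsets
#'
#' Cuts per-trial snippets of the dF/F matrix over a fixed window around
#' each movement onset (default -1 s before to +3 s after, the pre-movement
#' second serving as baseline). Trials whose window does not fit inside the
#' segment are dropped and reported.
#'
#' @param dff boutons-by-frames dF/F matrix.
#' @param onsets movement onsets, s.
#' @param labels trial labels ("RM"/"UM"), same length as `onsets`.
#' @param frame_rate Hz.
#' @param window alignment window in s relative to onset (default c(-1, 3)).
#' @return a `trial_tensor`: `activity` array boutons x trials x time,
#'   `time` axis (s relative to onset), `labels`, `onsets`, and the indices
#'   of dropped trials.
#' @export
align_trials <- function(dff, onsets, labels, frame_rate, window = c(-1, 3)) {
  stop_if_not(is.matrix(dff), "dff must be a boutons-by-frames matrix")
  stop_if_not(length(onsets) == length(labels),
              "onsets and labels must have equal length")
  n_frames <- ncol(dff)
  pre <- round(-window[1] * frame_rate)
  post <- round(window[2] * frame_rate)
  len <- pre + post + 1L

  onset_frame <- round(onsets * frame_rate) + 1L
  ok <- onset_frame - pre >= 1L & onset_frame + post <= n_frames
  dropped <- which(!ok)
  if (!any(ok)) stop("no trials survive the alignment window", call. = FALSE)

  keep <- which(ok)
  act <- array(NA_real_, dim = c(nrow(dff), length(keep), len))
  for (j in seq_along(keep)) {
    i0 <- onset_frame[keep[j]] - pre
    act[, j, ] <- dff[, i0:(i0 + len - 1L), drop = FALSE]
  }
  structure(list(
    activity = act,
    time = (seq_len(len) - 1L - pre) / frame_rate,
    labels = labels[keep],
    onsets = onsets[keep],
    frame_rate = frame_rate,
    dropped = dropped
  ), class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat("<trial_tensor>", dim(x$activity)[1], "boutons x",
      dim(x$activity)[2], "trials x", dim(x$activity)[3], "frames (",
      sum(x$labels == "RM"), "RM /", sum(x$labels == "UM"), "UM )\n")
  invisible(x)
}

# trial-averaged trace for one bouton and one label; NULL if no such trials
trial_average <- function(tensor, bouton, label) {
  sel <- tensor$labels == label
  if (!any(sel)) return(NULL)
  m <- tensor$activity[bouton, sel, , drop = FALSE]
  colMeans(matrix(m, nrow = sum(sel), ncol = dim(tensor$activity)[3]))
}

# responsiveness rule shared by bouton and axon classification: the peak of
# the trial-averaged trace in peak_window minus the 5th percentile of the
# averaged trace must exceed `threshold` (in the same units as the trace).
response_peak_stat <- function(avg, time, peak_window = c(-0.2, 3)) {
  in_win <- time >= peak_window[1] & time <= peak_window[2]
  max(avg[in_win]) - stats::quantile(avg, 0.05, names = FALSE)
}

classify_from_averages <- function(avg_rm, avg_um, time, threshold,
                                   peak_window = c(-0.2, 3)) {
  stat_rm <- if (is.null(avg_rm)) -Inf else
    response_peak_stat(avg_rm, time, peak_window)
  stat_um <- if (is.null(avg_um)) -Inf else
    response_peak_stat(avg_um, time, peak_window)
  rm_resp <- stat_rm > threshold
  um_resp <- stat_um > threshold
  cls <- if (rm_resp && um_resp) "both" else if (rm_resp) "RM_only" else
    if (um_resp) "UM_only" else "none"
  list(class = cls, peak_rm = stat_rm, peak_um = stat_um)
}

#' Classify a bouton by reward-outcome responsiveness
#'
#' A bouton is responsive to a trial type when the peak of its trial-averaged
#' dF/F (searched -0.2 to 3 s relative to movement onset) minus the 5th
#' percentile of the averaged trace exceeds 90% of the bouton's session
#' standard deviation. Responsiveness is evaluated independently for RM and
#' UM averages and combined into RM_only / UM_only / both / none.
#'
#' @param tensor a `trial_tensor`.
#' @param bouton bouton row index into the tensor.
#' @param session_sd sd of this bouton's dF/F over the full imaged segment.
#' @param sd_factor threshold in units of `session_sd` (default 0.9).
#' @param min_trials minimum RM and UM trials required (default 5); below it
#'   the bouton is flagged and classed "none".
#' @return list: class, peak_rm, peak_um (in sd units), threshold (sd units),
#'   insufficient (logical).
#' @export
classify_bouton <- function(tensor, bouton, session_sd, sd_factor = 0.9,
                            min_trials = 5) {
  stop_if_not(session_sd > 0, "session_sd must be positive")
  n_rm <- sum(tensor$labels == "RM"); n_um <- sum(tensor$labels == "UM")
  if (n_rm < min_trials || n_um < min_trials) {
    return(list(class = "none", peak_rm = NA_real_, peak_um = NA_real_,
                threshold = sd_factor, insufficient = TRUE))
  }
  avg_rm <- trial_average(tensor, bouton, "RM")
  avg_um <- trial_average(tensor, bouton, "UM")
  res <- classify_from_averages(avg_rm / session_sd, avg_um / session_sd,
                                tensor$time, sd_factor)
  c(res[c("class", "peak_rm", "peak_um")],
    list(threshold = sd_factor, insufficient = FALSE))
}

#' Classify every bouton of a tensor
#'
#' @param tensor a `trial_tensor`.
#' @param session_sds per-bouton session sds (full-segment dF/F sd).
#' @param ... passed to [classify_bouton()].
#' @return data frame: bouton, class, peak_rm, peak_um, insufficient.
#' @export
classify_boutons <- function(tensor, session_sds, ...) {
  n_b <- dim(tensor$activity)[1]
  stop_if_not(length(session_sds) == n_b,
              "need one session sd per bouton")
  rows <- lapply(seq_len(n_b), function(b) {
    r <- classify_bouton(tensor, b, session_sds[b], ...)
    data.frame(bouton = b, class = r$class, peak_rm = r$peak_rm,
               peak_um = r$peak_um, insufficient = r$insufficient)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram-derived responsiveness threshold for axons
#'
#' Builds histograms (bin width `bin`, in sd units, spanning from 0) of the
#' axon peak statistics in RM and UM trials, takes each distribution's mode
#' bin center (ties broken toward the lower bin), and returns the mean of
#' the two mode centers, capped at 1 sd.
#'
#' @param peaks_rm,peaks_um axon peak statistics in sd units.
#' @param bin histogram bin width in sd units (default 0.1).
#' @return threshold in sd units.
#' @export
axon_response_threshold <- function(peaks_rm, peaks_um, bin = 0.1) {
  stop_if_not(length(peaks_rm) >= 1 && length(peaks_um) >= 1,
              "need at least one peak value per distribution")
  mode_center <- function(v) {
    v <- pmax(v, 0)
    breaks <- seq(0, max(v) + bin, by = bin)
    counts <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
    i <- which.max(counts)  # which.max takes the first (lower) mode
    (breaks[i] + breaks[i + 1]) / 2
  }
  min(mean(c(mode_center(peaks_rm), mode_center(peaks_um))), 1)
}

#' Classify an axon by reward-outcome responsiveness
#'
#' Same rule as [classify_bouton()] but the responsiveness threshold comes
#' from [axon_response_threshold()] instead of the fixed 0.9 sd.
#'
#' @param avg_rm,avg_um the axon's trial-averaged traces in sd units (NULL if
#'   a trial type is absent).
#' @param time time axis of the averages, s relative to onset.
#' @param threshold threshold in sd units.
#' @return list: class, peak_rm, peak_um, threshold.
#' @export
classify_axon <- function(avg_rm, avg_um, time, threshold) {
  res <- classify_from_averages(avg_rm, avg_um, time, threshold)
  c(res, list(threshold = threshold))
}

#' Class composition of a bouton population
#'
#' @param classes character vector of classes.
#' @return named fractions over RM_only, UM_only, both, none (sums to 1).
#' @export
class_fractions <- function(classes) {
  stop_if_not(length(classes) > 0, "no classes given")
  lv <- c("RM_only", "UM_only", "both", "none")
  stop_if_not(all(classes %in% lv), "unknown class label")
  tab <- table(factor(classes, levels = lv))
  fr <- as.numeric(tab) / length(classes)
  names(fr) <- lv
  fr
}

#' Class transition matrix between learning stages
#'
#' @param early,late class vectors for the same boutons, in the same order.
#' @param ids optional bouton identifiers; must match between stages.
#' @return 4x4 matrix, rows = early class, columns = late class; each row
#'   with any boutons sums to 1.
#' @export
class_transition_matrix <- function(early, late, ids = NULL) {
  stop_if_not(length(early) == length(late),
              "early and late must cover the same boutons")
  if (!is.null(ids))
    stop_if_not(!anyDuplicated(ids) && length(ids) == length(early),
                "bouton identities must match between stages")
  lv <- c("RM_only", "UM_only", "both", "none")
  stop_if_not(all(c(early, late) %in% lv), "unknown class label")
  tab <- table(factor(early, levels = lv), factor(late, levels = lv))
  m <- unclass(tab)
  rs <- rowSums(m)
  m <- sweep(m, 1, pmax(rs, 1), "/")
  m[rs == 0, ] <- NA_real_
  m
}
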