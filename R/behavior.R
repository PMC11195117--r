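#' Detect lever-movement bouts
#'
#' Finds contiguous runs where the lever position exceeds a rest threshold.
#' Onset is the first threshold crossing, offset the sample where the lever
#' falls back below it (half-open interval). Bouts separated by less than
#' `merge_gap` are considered one continuous movement and merged.
#'
#' When `rest_threshold` is `NULL` it is estimated as mean + `k_rest` sd of
#' the lever position over the putative rest period (samples below the
#' session median), separating resting from movement.
#'
#' @param session a `lever_session`.
#' @param rest_threshold mm; `NULL` to estimate from the rest period.
#' @param merge_gap s; bouts closer than this are combined (default 0.5).
#' @param k_rest sd multiplier for the estimated rest threshold. The default
#'   of 8 keeps the threshold well above the sensor noise floor (a small
#'   multiplier would cross at chance on every rest period) while staying an
#'   order of magnitude below genuine push amplitudes.
#' @return data frame of bouts (onset, offset, peak_mm), sorted by onset;
#'   empty if the trace never crosses the threshold.
#' @export
detect_bouts <- function(session, rest_threshold = NULL, merge_gap = 0.5,
                         k_rest = 8) {
  stop_if_not(inherits(session, "lever_session"),
              "session must be a lever_session")
  pos <- session$positions
  sr <- session$sample_rate
  if (is.null(rest_threshold)) {
    rest <- pos[pos <= stats::median(pos)]
    rest_threshold <- mean(rest) + k_rest * stats::sd(rest)
  }
  stop_if_not(rest_threshold > 0, "rest_threshold must be positive")

  above <- pos > rest_threshold
  if (!any(above)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      peak_mm = numeric(0)))
  }
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L)  # first sample back below threshold
  onset <- (starts - 1) / sr
  offset <- (ends - 1) / sr

  # merge bouts separated by < merge_gap
  if (length(onset) > 1) {
    keep_on <- onset[1]
    merged_on <- numeric(0); merged_off <- numeric(0)
    cur_off <- offset[1]
    for (i in seq_along(onset)[-1]) {
      if (onset[i] - cur_off < merge_gap) {
        cur_off <- offset[i]
      } else {
        merged_on <- c(merged_on, keep_on); merged_off <- c(merged_off, cur_off)
        keep_on <- onset[i]; cur_off <- offset[i]
      }
    }
    merged_on <- c(merged_on, keep_on); merged_off <- c(merged_off, cur_off)
    onset <- merged_on; offset <- merged_off
  }

  peak <- vapply(seq_along(onset), function(i) {
    idx <- which((seq_along(pos) - 1) / sr >= onset[i] &
                   (seq_along(pos) - 1) / sr < offset[i])
    if (length(idx)) max(pos[idx]) else NA_real_
  }, 0)
  data.frame(onset = onset, offset = offset, peak_mm = peak)
}

#' Label bouts as rewarded or un-rewarded movements
#'
#' A bout is a rewarded movement (RM) iff its peak displacement reaches the
#' push threshold and its onset falls inside a cue-initiated task period;
#' any other push (sub-threshold in the task period, or un-cued during the
#' inter-trial interval) is an un-rewarded movement (UM). A reward ends the
#' trial, so only the first supra-threshold bout of each cue window is RM;
#' bouts starting later in the nominal window are already in the inter-trial
#' interval and count as un-cued UM.
#'
#' @param bouts data frame from [detect_bouts()].
#' @param session the `lever_session` the bouts came from.
#' @return `bouts` with `label` ("RM"/"UM") and `in_task_period` columns.
#' @export
label_bouts <- function(bouts, session) {
  if (!nrow(bouts)) {
    bouts$label <- character(0); bouts$in_task_period <- logical(0)
    return(bouts)
  }
  label <- rep("UM", nrow(bouts))
  in_task <- rep(FALSE, nrow(bouts))
  for (cue in session$cue_onsets) {
    win <- which(bouts$onset >= cue &
                   bouts$onset < cue + session$task_period)
    if (!length(win)) next
    supra <- win[bouts$peak_mm[win] >= session$push_threshold]
    if (length(supra)) {
      rm_i <- supra[1]
      label[rm_i] <- "RM"
      in_task[win[win <= rm_i]] <- TRUE  # reward closes the task period
    } else {
      in_task[win] <- TRUE
    }
  }
  bouts$label <- label
  bouts$in_task_period <- in_task
  bouts
}

#' Exclude bouts without a clean pre-movement baseline
#'
#' Drops any bout preceded by another movement within `window` seconds
#' (i.e. another bout's offset falls inside the `window` before its onset),
#' so the pre-movement baseline is uncontaminated.
#'
#' @param bouts sorted bout data frame.
#' @param window s (default 3).
#' @return subset of `bouts` with clean baselines (`clean_baseline` column
#'   added to the input rows retained).
#' @export
filter_clean_baseline <- function(bouts, window = 3) {
  if (!nrow(bouts)) { bouts$clean_baseline <- logical(0); return(bouts) }
  stop_if_not(!is.unsorted(bouts$onset), "bouts must be sorted by onset")
  clean <- vapply(seq_len(nrow(bouts)), function(i) {
    others <- bouts[-i, , drop = FALSE]
    !any(others$offset > bouts$onset[i] - window &
           others$offset <= bouts$onset[i])
  }, TRUE)
  bouts$clean_baseline <- clean
  bouts[clean, , drop = FALSE]
}

#' Extract an aligned movement trajectory for a bout
#'
#' @param session a `lever_session`.
#' @param onset bout onset, s.
#' @param window alignment window (s) relative to onset, default -0.5..+1.5.
#' @param n_points number of samples after linear resampling.
#' @return numeric trajectory of length `n_points`.
#' @export
bout_trajectory <- function(session, onset, window = c(-0.5, 1.5),
                            n_points = 64) {
  sr <- session$sample_rate
  tq <- seq(window[1], window[2], length.out = n_points) + onset
  tgrid <- (seq_along(session$positions) - 1) / sr
  stats::approx(tgrid, session$positions, xout = tq, rule = 2)$y
}

#' Pearson correlation between two movement trajectories
#'
#' @param traj_i,traj_j trajectories resampled to a common alignment window.
#' @return Pearson r.
#' @export
movement_correlation <- function(traj_i, traj_j) {
  stop_if_not(length(traj_i) == length(traj_j),
              "trajectories must have equal length")
  stop_if_not(stats::sd(traj_i) > 0 && stats::sd(traj_j) > 0,
              "correlation undefined for a zero-variance trajectory")
  stats::cor(traj_i, traj_j)
}

#' Session-level behavioral metrics
#'
#' Success rate = rewarded trials / cued trials; reaction time = median
#' cue-to-threshold-crossing latency over rewarded trials; ITI push count =
#' UM bouts outside any task period.
#'
#' @param session a `lever_session`.
#' @param bouts labeled bouts ([label_bouts()]).
#' @return list(success_rate, reaction_time, iti_push_count).
#' @export
behavior_metrics <- function(session, bouts) {
  n_cues <- length(session$cue_onsets)
  stop_if_not(n_cues > 0, "success rate undefined without cued trials")
  rm_bouts <- bouts[bouts$label == "RM", , drop = FALSE]
  rewarded_cues <- vapply(session$cue_onsets, function(cue)
    any(rm_bouts$onset >= cue & rm_bouts$onset < cue + session$task_period),
    TRUE)
  # latency from cue to first threshold crossing of its rewarding bout
  latency <- vapply(session$cue_onsets[rewarded_cues], function(cue) {
    on <- rm_bouts$onset[rm_bouts$onset >= cue &
                           rm_bouts$onset < cue + session$task_period][1]
    on - cue
  }, 0)
  list(
    success_rate = mean(rewarded_cues),
    reaction_time = if (length(latency)) stats::median(latency) else NA_real_,
    iti_push_count = sum(bouts$label == "UM" & !bouts$in_task_period)
  )
}
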