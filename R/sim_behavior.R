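#' Simulate a cued lever-pushing session
#'
#' Generates a lever-position trace with cue onsets and ground-truth movement
#' bouts. Each trial starts with a cue; with probability `p_success` the
#' simulated mouse pushes past `push_threshold` within the task period and is
#' rewarded (an RM bout), otherwise it may make a sub-threshold push (UM) or
#' none. During each inter-trial interval an un-cued push occurs with
#' probability `p_iti_push` (always UM; it incurs an extra timeout of one ITI).
#' Successive pushes are separated by more than 0.5 s by construction.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to the config seed.
#' @return a `lever_session`: lever positions (mm) at the imaging frame rate,
#'   cue onsets (s), task parameters and a `truth` data frame of ground-truth
#'   bouts (onset, offset, peak_mm, label, during_iti).
#' @export
simulate_behavior <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  sr <- config$frame_rate
  duration <- session_duration(config)
  n <- config$n_frames * config$n_segments
  tgrid <- (seq_len(n) - 1) / sr

  pos <- stats::rnorm(n, 0, config$lever_noise_sd)
  cues <- numeric(0)
  bouts <- list()

  add_push <- function(onset, peak_mm) {
    dur <- stats::runif(1, 0.4, 0.8)
    idx <- which(tgrid >= onset & tgrid < onset + dur)
    if (length(idx) < 2) return(NULL)
    # raised-cosine bump peaking mid-push
    phase <- (tgrid[idx] - onset) / dur
    pos[idx] <<- pos[idx] + peak_mm * 0.5 * (1 - cos(2 * pi * phase))
    list(onset = onset, offset = onset + dur, peak_mm = peak_mm)
  }

  thr <- config$push_threshold
  t <- 1.0
  while (t + config$task_period + config$iti_duration < duration - 2) {
    cues <- c(cues, t)
    trial_end <- t + config$task_period
    if (stats::runif(1) < config$p_success) {
      latency <- stats::runif(1, 0.4, min(2.5, config$task_period - 1.5))
      p <- add_push(t + latency, stats::runif(1, 1.1, 1.8) * thr)
      if (!is.null(p)) {
        bouts[[length(bouts) + 1L]] <- c(p, label = "RM", during_iti = FALSE)
        trial_end <- p$offset + 0.2  # reward ends the task period early
      }
    } else if (stats::runif(1) < config$p_fail_push) {
      latency <- stats::runif(1, 0.4, config$task_period - 1.5)
      p <- add_push(t + latency, stats::runif(1, 0.3, 0.8) * thr)
      if (!is.null(p))
        bouts[[length(bouts) + 1L]] <- c(p, label = "UM", during_iti = FALSE)
    }
    iti <- config$iti_duration
    if (stats::runif(1) < config$p_iti_push) {
      # late in the ITI, > 3 s after the last push, so the pre-movement
      # baseline stays clean; the timeout below extends the ITI past it
      onset <- trial_end + stats::runif(1, 3.2, 3.9)
      p <- add_push(onset, stats::runif(1, 0.5, 1.5) * thr)
      if (!is.null(p)) {
        bouts[[length(bouts) + 1L]] <- c(p, label = "UM", during_iti = TRUE)
        iti <- iti * 2  # timeout penalty
      }
    }
    t <- trial_end + iti
  }

  truth <- if (length(bouts)) {
    data.frame(
      onset = vapply(bouts, `[[`, 0, "onset"),
      offset = vapply(bouts, `[[`, 0, "offset"),
      peak_mm = vapply(bouts, `[[`, 0, "peak_mm"),
      label = vapply(bouts, `[[`, "", "label"),
      during_iti = vapply(bouts, `[[`, FALSE, "during_iti")
    )
  } else {
    data.frame(onset = numeric(0), offset = numeric(0), peak_mm = numeric(0),
               label = character(0), during_iti = logical(0))
  }
  truth <- truth[order(truth$onset), , drop = FALSE]
  rownames(truth) <- NULL

  structure(list(
    positions = pos, sample_rate = sr, cue_onsets = cues,
    task_period = config$task_period, push_threshold = thr,
    iti_duration = config$iti_duration, duration = duration, truth = truth
  ), class = "lever_session")
}

#' @export
print.lever_session <- function(x, ...) {
  cat("<lever_session>", round(x$duration), "s,", length(x$cue_onsets),
      "cues,", nrow(x$truth), "ground-truth bouts\n")
  invisible(x)
}
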