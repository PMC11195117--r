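#' Calcium transient kernel
#'
#' Difference of exponentials `exp(-t/decay) - exp(-t/rise)` normalized to a
#' unit peak, sampled on the frame grid. Mimics GCaMP6s kinetics (fast rise,
#' slow decay).
#'
#' @param rise,decay time constants, s (`0 < rise < decay`).
#' @param frame_rate Hz.
#' @param span kernel support in decay constants (default 6).
#' @return numeric vector of kernel samples starting at lag 0.
#' @export
transient_kernel <- function(rise, decay, frame_rate, span = 6) {
  stop_if_not(rise > 0 && decay > rise, "need 0 < rise < decay")
  t <- seq(0, span * decay, by = 1 / frame_rate)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

# add amp * kernel starting at the frame nearest to `time` into trace
add_transient <- function(trace, kernel, time, amp, frame_rate) {
  i0 <- round(time * frame_rate) + 1L
  if (i0 > length(trace)) return(trace)
  i1 <- min(length(trace), i0 + length(kernel) - 1L)
  if (i0 < 1L) {
    koff <- 1L - i0
    i0 <- 1L
    seg <- kernel[(koff + 1L):min(length(kernel), koff + (i1 - i0 + 1L))]
  } else {
    seg <- kernel[seq_len(i1 - i0 + 1L)]
  }
  trace[i0:(i0 + length(seg) - 1L)] <- trace[i0:(i0 + length(seg) - 1L)] +
    amp * seg
  trace
}

#' Simulate bouton fluorescence for a behavioral session
#'
#' Each axon carries a shared spontaneous event train; each of its boutons
#' realizes a shared event with probability `p_shared` and adds bouton-unique
#' events at `unique_event_rate`. Boutons are assigned an outcome class
#' (RM-only / UM-only / both / none) and receive a transient of amplitude
#' `response_gain` at each preferred movement onset. Transients are kernel
#' convolutions on a constant positive per-bouton baseline, plus Gaussian
#' noise of sd `noise_sd` (in dF/F units).
#'
#' @param config a [sim_config()].
#' @param behavior a `lever_session` from [simulate_behavior()] (same frame
#'   rate and duration).
#' @param seed integer seed.
#' @return a list with `fluor` (a `fluor_set`: raw boutons-by-frames matrix,
#'   frame rate, bouton/axon ids) and `truth` (bouton classes and the
#'   ground-truth event log with per-event origin).
#' @export
simulate_fluorescence <- function(config, behavior, seed = config$seed) {
  validate_sim_config(config)
  stop_if_not(inherits(behavior, "lever_session"),
              "behavior must be a lever_session")
  stop_if_not(isTRUE(all.equal(behavior$sample_rate, config$frame_rate)) &&
                isTRUE(all.equal(behavior$duration, session_duration(config))),
              "behavior and config disagree on frame rate or duration")
  set.seed(as.integer(seed))

  fr <- config$frame_rate
  n <- config$n_frames * config$n_segments
  duration <- behavior$duration
  n_b <- config$n_axons * config$boutons_per_axon
  axon_of <- rep(seq_len(config$n_axons), each = config$boutons_per_axon)
  bouton_ids <- seq_len(n_b)
  kernel <- transient_kernel(config$transient_rise, config$transient_decay, fr)
  peak_lag <- (which.max(kernel) - 1) / fr  # onset-to-peak lag of the kernel

  classes <- sample(c("RM_only", "UM_only", "both", "none"), n_b,
                    replace = TRUE,
                    prob = c(config$frac_rm_only, config$frac_um_only,
                             config$frac_both,
                             1 - config$frac_rm_only - config$frac_um_only -
                               config$frac_both))
  truth_bouts <- behavior$truth
  rm_onsets <- truth_bouts$onset[truth_bouts$label == "RM"]
  um_onsets <- truth_bouts$onset[truth_bouts$label == "UM"]

  shared <- lapply(seq_len(config$n_axons), function(a)
    rpoisson_train(config$shared_event_rate, duration, config$min_event_gap))

  raw <- matrix(0, n_b, n)
  baselines <- stats::runif(n_b, config$baseline_range[1],
                            config$baseline_range[2])
  ev <- vector("list", n_b)

  for (b in seq_len(n_b)) {
    a <- axon_of[b]
    sh <- shared[[a]]
    keep <- stats::runif(length(sh)) < config$p_shared
    times <- sh[keep]
    origin <- rep("shared", sum(keep))
    uq <- rpoisson_train(config$unique_event_rate, duration,
                         config$min_event_gap)
    times <- c(times, uq)
    origin <- c(origin, rep("unique", length(uq)))
    amps <- if (length(times)) stats::runif(length(times), 0.4, 1.0)
            else numeric(0)

    resp <- numeric(0)
    if (classes[b] %in% c("RM_only", "both")) resp <- c(resp, rm_onsets)
    if (classes[b] %in% c("UM_only", "both")) resp <- c(resp, um_onsets)
    if (length(resp)) {
      resp <- resp + config$response_latency
      times <- c(times, resp)
      origin <- c(origin, rep("response", length(resp)))
      amps <- c(amps, rep(config$response_gain, length(resp)))
    }

    # drop events too close to the segment end for their peak to be emitted
    late_ok <- times <= duration - 1
    times <- times[late_ok]; origin <- origin[late_ok]; amps <- amps[late_ok]

    # enforce the refractory gap across the bouton's combined trains so
    # every emitted transient is an isolated, detectable event; response
    # events take precedence over spontaneous ones, shared over unique
    if (length(times) > 1) {
      prio <- match(origin, c("response", "shared", "unique"))
      ord <- order(prio, times)
      kept_t <- numeric(0); keep <- logical(length(times))
      for (i in ord) {
        if (!length(kept_t) ||
              min(abs(kept_t - times[i])) >= config$min_event_gap) {
          keep[i] <- TRUE
          kept_t <- c(kept_t, times[i])
        }
      }
      times <- times[keep]; origin <- origin[keep]; amps <- amps[keep]
    }

    sig <- numeric(n)
    for (i in seq_along(times))
      sig <- add_transient(sig, kernel, times[i], amps[i], fr)
    raw[b, ] <- baselines[b] * (1 + sig) +
      stats::rnorm(n, 0, config$noise_sd * baselines[b])

    ev[[b]] <- if (length(times)) {
      o <- order(times)
      data.frame(bouton_id = b, axon_id = a, time = times[o],
                 peak_time = times[o] + peak_lag,
                 amplitude = amps[o], origin = origin[o])
    } else NULL
  }

  events <- do.call(rbind, ev[!vapply(ev, is.null, TRUE)])
  if (is.null(events))
    events <- data.frame(bouton_id = integer(0), axon_id = integer(0),
                         time = numeric(0), peak_time = numeric(0),
                         amplitude = numeric(0), origin = character(0))
  rownames(events) <- NULL

  fluor <- structure(list(
    raw = raw, frame_rate = fr, bouton_ids = bouton_ids, axon_of = axon_of,
    day = NA_integer_, baselines = baselines
  ), class = "fluor_set")

  list(fluor = fluor,
       truth = list(
         classes = data.frame(bouton_id = bouton_ids, axon_id = axon_of,
                              class = classes),
         events = events))
}

#' @export
print.fluor_set <- function(x, ...) {
  cat("<fluor_set>", nrow(x$raw), "boutons x", ncol(x$raw), "frames @",
      x$frame_rate, "Hz\n")
  invisible(x)
}
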