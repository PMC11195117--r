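#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_behavior()],
#' [simulate_fluorescence()] and [simulate_structure()]. Defaults emulate a
#' head-fixed cued lever-pushing session imaged at ~15 Hz with GCaMP6s-like
#' kinetics (fast rise ~0.2 s, slow decay ~1 s) and every-other-day
#' structural imaging over 11 days.
#'
#' @param n_axons number of simulated axons.
#' @param boutons_per_axon boutons on each axon.
#' @param frame_rate imaging frame rate in Hz.
#' @param n_frames frames per continuous imaged segment.
#' @param n_segments number of concatenated segments (the session duration is
#'   `n_frames * n_segments / frame_rate` seconds).
#' @param transient_rise,transient_decay rise and decay time constants (s) of
#'   the difference-of-exponentials calcium transient kernel.
#' @param noise_sd additive Gaussian noise, in dF/F units.
#' @param baseline_range range (arbitrary units) of the constant per-bouton
#'   baseline fluorescence.
#' @param p_shared probability that an axon-level event is realized in a given
#'   bouton (1 - p_shared is the bouton-local failure rate).
#' @param shared_event_rate axon-level spontaneous event rate, Hz.
#' @param unique_event_rate bouton-local event rate, Hz per bouton.
#' @param min_event_gap refractory spacing (s) enforced between events of one
#'   train so that the 670-ms peak-matching rule is unambiguous.
#' @param frac_rm_only,frac_um_only,frac_both probabilities that a bouton is
#'   selective for rewarded movements only, un-rewarded movements only, or
#'   both; the remainder is non-responsive. Must sum to at most 1.
#' @param response_gain dF/F peak amplitude added at each preferred-outcome
#'   movement onset.
#' @param response_latency latency (s) from movement onset to the response
#'   transient.
#' @param trial_interval nominal cue-to-cue interval (s) when no early reward
#'   shortens the trial.
#' @param p_success probability a cued trial contains a supra-threshold push.
#' @param p_fail_push probability a failed cued trial still contains a
#'   sub-threshold push.
#' @param p_iti_push probability of an un-cued push in a given inter-trial
#'   interval.
#' @param push_threshold lever threshold in mm (rewarded if exceeded in the
#'   task period).
#' @param task_period response window after the cue, s.
#' @param iti_duration inter-trial interval, s.
#' @param lever_noise_sd sensor noise on the lever trace, mm.
#' @param days imaging days of the structural experiment.
#' @param axon_length_um length of each imaged axon segment, micrometres.
#' @param baseline_density initial bouton density, boutons per micrometre.
#' @param formation_rate,elimination_rate per-interval probabilities that a
#'   bouton forms (relative to the number present) or is eliminated.
#' @param cluster_scale_um spatial scale (um) for placing newly formed boutons
#'   near existing ones; `Inf` places them uniformly.
#' @param group `"training"` or `"control"` label carried on structural output.
#' @param seed default master seed used when an operation is not given one.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_axons = 8,
                       boutons_per_axon = 5,
                       frame_rate = 15,
                       n_frames = 4000,
                       n_segments = 1,
                       transient_rise = 0.2,
                       transient_decay = 1.0,
                       noise_sd = 0.05,
                       baseline_range = c(50, 150),
                       p_shared = 0.8,
                       shared_event_rate = 0.08,
                       unique_event_rate = 0.02,
                       min_event_gap = 1,
                       frac_rm_only = 0.3,
                       frac_um_only = 0.2,
                       frac_both = 0.2,
                       response_gain = 0.6,
                       response_latency = 0.15,
                       trial_interval = 14,
                       p_success = 0.7,
                       p_fail_push = 0.7,
                       p_iti_push = 0.3,
                       push_threshold = 1.5,
                       task_period = 10,
                       iti_duration = 4,
                       lever_noise_sd = 0.02,
                       days = c(0, 2, 4, 6, 8, 10),
                       axon_length_um = 60,
                       baseline_density = 0.35,
                       formation_rate = 0.08,
                       elimination_rate = 0.06,
                       cluster_scale_um = Inf,
                       group = "training",
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if_not(cfg$frame_rate > 0, "frame_rate must be positive")
  stop_if_not(cfg$n_frames >= 2 && cfg$n_segments >= 1,
              "n_frames/n_segments must be positive")
  probs <- c(cfg$p_shared, cfg$p_success, cfg$p_fail_push, cfg$p_iti_push,
             cfg$frac_rm_only, cfg$frac_um_only, cfg$frac_both,
             cfg$formation_rate, cfg$elimination_rate)
  stop_if_not(all(probs >= 0 & probs <= 1),
              "probabilities must lie in [0, 1]")
  stop_if_not(cfg$frac_rm_only + cfg$frac_um_only + cfg$frac_both <= 1,
              "class fractions must sum to at most 1")
  rates <- c(cfg$shared_event_rate, cfg$unique_event_rate, cfg$noise_sd,
             cfg$lever_noise_sd)
  stop_if_not(all(rates >= 0), "rates and noise levels must be non-negative")
  stop_if_not(cfg$transient_rise > 0 && cfg$transient_decay > cfg$transient_rise,
              "need 0 < transient_rise < transient_decay")
  stop_if_not(cfg$push_threshold > 0 && cfg$task_period > 0 &&
                cfg$iti_duration > 0, "behavior timings must be positive")
  stop_if_not(cfg$axon_length_um > 0, "axon_length_um must be positive")
  stop_if_not(length(cfg$days) >= 2 && !is.unsorted(cfg$days, strictly = TRUE),
              "days must be >= 2 strictly increasing values")
  stop_if_not(cfg$group %in% c("training", "control"),
              "group must be 'training' or 'control'")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_axons, "axons x", x$boutons_per_axon,
      "boutons,", x$n_frames, "frames @", x$frame_rate, "Hz,",
      length(x$days), "structural days\n")
  invisible(x)
}

session_duration <- function(cfg) cfg$n_frames * cfg$n_segments / cfg$frame_rate
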