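#' Pipeline configuration
#'
#' Bundles stage parameters for a two-stage (early vs late learning)
#' simulated experiment with several replicate mice. The early and late
#' configs differ, by default, in the direction motor learning moves the
#' real quantities: higher success rate, stronger and more RM-shifted
#' selectivity, and higher shared-event probability late.
#'
#' @param early,late [sim_config()]s for the two learning stages.
#' @param n_mice replicate simulated mice per stage.
#' @param seed master seed; per-mouse substreams are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(
    early = sim_config(p_success = 0.4, frac_rm_only = 0.2,
                       frac_um_only = 0.3, p_shared = 0.65),
    late = sim_config(p_success = 0.8, frac_rm_only = 0.4,
                      frac_um_only = 0.1, p_shared = 0.85),
    n_mice = 3,
    seed = 1L) {
  stop_if_not(n_mice >= 1, "need at least one mouse")
  structure(list(early = early, late = late, n_mice = as.integer(n_mice),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `early`, `late` (each holding [sim_config()] arguments),
#' `n_mice` and `seed`; missing values fall back to the defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(args) do.call(sim_config, args %||% list())
  pipeline_config(
    early = mk(y$early),
    late = mk(y$late),
    n_mice = y$n_mice %||% 3,
    seed = y$seed %||% 1L)
}

#' Analyze one simulated imaging session end to end
#'
#' Runs the full single-session analysis: bout detection and labeling with
#' baseline cleaning, dF/F and event detection, trial alignment, bouton
#' classification, same-axon same-peak fraction and axon heterogeneity,
#' segment PCA with trajectory selectivity, and the activated-ensemble
#' statistic binned by movement correlation.
#'
#' @param fluor a `fluor_set`.
#' @param behavior the matching `lever_session`.
#' @param min_trials minimum trials per outcome for classification.
#' @param max_pairs cap on trial pairs entering the pairwise statistics.
#' @return list of per-session tables and summary scalars.
#' @export
analyze_session <- function(fluor, behavior, min_trials = 5,
                            max_pairs = 400) {
  bouts <- label_bouts(detect_bouts(behavior), behavior)
  clean <- filter_clean_baseline(bouts)
  metrics <- behavior_metrics(behavior, bouts)

  dff <- compute_dff(fluor$raw, fluor$frame_rate)
  session_sds <- apply(dff, 1, stats::sd)
  events <- detect_events_all(fluor)

  tensor <- align_trials(dff, clean$onset, clean$label, fluor$frame_rate)
  classes <- classify_boutons(tensor, session_sds, min_trials = min_trials)
  fractions <- class_fractions(classes$class)

  pairs <- same_axon_pair_fractions(events)
  same_frac <- if (nrow(pairs)) aggregate_same_fraction(pairs)$mouse else
    NA_real_
  het <- vapply(split(classes$class, fluor$axon_of), axon_heterogeneity, 0)
  mean_het <- if (all(is.na(het))) NA_real_ else mean(het, na.rm = TRUE)

  pca <- segment_pca(dff)
  traj <- extract_trajectories(pca$pcs, clean$onset, clean$label,
                               fluor$frame_rate)
  sel <- if (!is.null(traj$mean_rm) && !is.null(traj$mean_um))
    selectivity_indices(traj) else NULL

  # pairwise movement / ensemble statistics over clean trials
  responsive <- fluor$bouton_ids[classes$class != "none"]
  trajs <- lapply(clean$onset, function(on) bout_trajectory(behavior, on))
  counts <- vapply(clean$onset, function(on)
    activated_count(events, on, responsive), 0L)
  n_t <- nrow(clean)
  pair_rows <- list()
  if (n_t >= 2) {
    all_pairs <- utils::combn(n_t, 2)
    if (ncol(all_pairs) > max_pairs)
      all_pairs <- all_pairs[, seq_len(max_pairs), drop = FALSE]
    for (c_i in seq_len(ncol(all_pairs))) {
      i <- all_pairs[1, c_i]; j <- all_pairs[2, c_i]
      if (stats::sd(trajs[[i]]) == 0 || stats::sd(trajs[[j]]) == 0) next
      if (counts[i] + counts[j] == 0) next
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        trial_i = i, trial_j = j,
        movement_r = movement_correlation(trajs[[i]], trajs[[j]]),
        ensemble_diff = ensemble_difference(counts[i], counts[j]))
    }
  }
  pair_stats <- do.call(rbind, pair_rows)
  binned <- if (!is.null(pair_stats))
    bin_by_movement_correlation(pair_stats$movement_r,
                                pair_stats$ensemble_diff) else NULL

  list(
    bouts = bouts, clean_bouts = clean, metrics = metrics,
    events = events, classes = classes, fractions = fractions,
    pair_fractions = pairs, same_peak_fraction = same_frac,
    heterogeneity = het, mean_heterogeneity = mean_het,
    selectivity = sel,
    mean_selectivity = if (!is.null(sel)) mean(sel$selectivity) else NA_real_,
    explained = pca$explained, pair_stats = pair_stats, binned = binned
  )
}

#' Run the simulated two-stage pipeline
#'
#' Simulates `n_mice` mice per learning stage, analyzes every session with
#' [analyze_session()], simulates and quantifies structural tracks, writes
#' all stage outputs as TSV under `outdir`, and records provenance
#' (package version, seed, config) in `run_log.yaml`. Identical config and
#' seed reproduce identical tables.
#'
#' @param config a `pipeline_config`.
#' @param outdir output directory (created if needed).
#' @param seed master seed; defaults to the config seed.
#' @return invisibly, the per-mouse summary data frame.
#' @export
run_pipeline <- function(config, outdir, seed = config$seed) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (stage in c("early", "late")) {
    cfg <- config[[stage]]
    for (m in seq_len(config$n_mice)) {
      mseed <- (as.integer(seed) + 7919L * m +
                  1299709L * (stage == "late")) %% 2000000000L
      beh <- simulate_behavior(cfg, substream_seed(mseed, "behavior"))
      sim <- simulate_fluorescence(cfg, beh,
                                   substream_seed(mseed, "fluorescence"))
      res <- analyze_session(sim$fluor, beh)
      st <- simulate_structure(cfg, substream_seed(mseed, "structure"))
      dens <- density_timecourse(st$track)
      rates <- turnover_rates(annotate_dynamics(st$track))

      stem <- file.path(outdir, sprintf("%s_mouse%02d", stage, m))
      write_tsv_table(res$bouts, paste0(stem, "_bouts.tsv"))
      write_tsv_table(res$events, paste0(stem, "_events.tsv"))
      write_tsv_table(res$classes, paste0(stem, "_classes.tsv"))
      if (!is.null(res$selectivity))
        write_tsv_table(res$selectivity, paste0(stem, "_selectivity.tsv"))
      if (!is.null(res$pair_stats))
        write_tsv_table(res$pair_stats, paste0(stem, "_pairs.tsv"))
      write_tsv_table(dens, paste0(stem, "_density.tsv"))
      write_tsv_table(rates, paste0(stem, "_turnover.tsv"))

      rows[[length(rows) + 1L]] <- data.frame(
        stage = stage, mouse = m,
        success_rate = res$metrics$success_rate,
        frac_rm_only = res$fractions["RM_only"],
        frac_um_only = res$fractions["UM_only"],
        frac_both = res$fractions["both"],
        same_peak_fraction = res$same_peak_fraction,
        mean_selectivity = res$mean_selectivity,
        mean_heterogeneity = res$mean_heterogeneity,
        mean_formation_pct = mean(rates$formation_pct, na.rm = TRUE),
        mean_elimination_pct = mean(rates$elimination_pct, na.rm = TRUE),
        mean_norm_density_last = mean(
          dens$norm_density[dens$day == max(dens$day)], na.rm = TRUE))
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  write_tsv_table(summary, file.path(outdir, "mouse_summary.tsv"))
  yaml::write_yaml(list(
    package = "boutonpipe",
    version = as.character(utils::packageVersion("boutonpipe")),
    seed = as.integer(seed),
    n_mice = config$n_mice,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), file.path(outdir, "run_log.yaml"))
  invisible(summary)
}

#' Early-vs-late summary report
#'
#' Reads the per-mouse summary of a [run_pipeline()] directory and compares
#' every metric between the early and late stages with two-sided Wilcoxon
#' rank-sum tests, reporting mean +/- SEM per stage and the raw p-value
#' (thresholds * p < 0.05, ** p < 0.01, *** p < 0.001; no multiplicity
#' correction). Tests are skipped, with a notice, when either stage has
#' fewer than 3 mice.
#'
#' @param outdir a [run_pipeline()] output directory.
#' @return data frame (also written to `report.tsv` in `outdir`):
#'   metric, early_mean, early_sem, late_mean, late_sem, p_value, signif.
#' @export
summary_report <- function(outdir) {
  path <- file.path(outdir, "mouse_summary.tsv")
  stop_if_not(file.exists(path),
              "missing mouse_summary.tsv: run the pipeline stage first")
  s <- read_tsv_table(path)
  metrics <- setdiff(names(s), c("stage", "mouse"))
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  enough <- min(table(s$stage)) >= 3
  if (!enough)
    message("fewer than 3 mice per stage: rank-sum tests skipped")
  rows <- lapply(metrics, function(mt) {
    e <- s[[mt]][s$stage == "early"]; l <- s[[mt]][s$stage == "late"]
    e <- e[!is.na(e)]; l <- l[!is.na(l)]
    p <- if (enough && length(e) >= 3 && length(l) >= 3)
      stats::wilcox.test(e, l, exact = FALSE)$p.value else NA_real_
    data.frame(metric = mt,
               early_mean = mean(e), early_sem = sem(e),
               late_mean = mean(l), late_sem = sem(l),
               p_value = p,
               signif = if (is.na(p)) "" else
                 if (p < 0.001) "***" else if (p < 0.01) "**" else
                   if (p < 0.05) "*" else "NS")
  })
  report <- do.call(rbind, rows)
  write_tsv_table(report, file.path(outdir, "report.tsv"))
  report
}
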