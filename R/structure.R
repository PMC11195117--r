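#' Annotate bouton dynamics between adjacent sessions
#'
#' For every bouton and every adjacent pair of imaging days, assigns exactly
#' one state: `persistent` (present -> present), `formed` (absent ->
#' present), `eliminated` (present -> absent) or `absent` (absent ->
#' absent). A presence gap (present, absent, present) is an elimination
#' followed by a formation.
#'
#' @param track a `bouton_track`.
#' @return data frame: bouton_id, axon_id, from_day, to_day, state.
#' @export
annotate_dynamics <- function(track) {
  stop_if_not(length(track$days) >= 2, "need at least two sessions")
  p <- track$presence
  n_days <- length(track$days)
  rows <- lapply(seq_len(n_days - 1L), function(d) {
    before <- p[, d]; after <- p[, d + 1L]
    state <- ifelse(before & after, "persistent",
                    ifelse(!before & after, "formed",
                           ifelse(before & !after, "eliminated", "absent")))
    data.frame(bouton_id = track$boutons$bouton_id,
               axon_id = track$boutons$axon_id,
               from_day = track$days[d], to_day = track$days[d + 1L],
               state = state)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bouton density time course per axon
#'
#' Density on day d is the number of boutons present divided by the axon
#' length; normalized density divides by the first-day density (NA for
#' axons with no boutons on the first day).
#'
#' @param track a `bouton_track`.
#' @return data frame: axon_id, day, n_present, density (per um),
#'   norm_density.
#' @export
density_timecourse <- function(track) {
  stop_if_not(all(track$axons$length_um > 0), "axon length must be positive")
  rows <- lapply(track$axons$axon_id, function(a) {
    sel <- track$boutons$axon_id == a
    len <- track$axons$length_um[track$axons$axon_id == a]
    n_pres <- colSums(track$presence[sel, , drop = FALSE])
    dens <- n_pres / len
    data.frame(axon_id = a, day = track$days, n_present = n_pres,
               density = dens,
               norm_density = if (dens[1] > 0) dens / dens[1] else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Formation and elimination percentages per interval
#'
#' Formation% into day d = 100 * formed(d-2 -> d) / present(d-2), and
#' analogously for elimination, per axon. Undefined (NA) when no bouton was
#' present at the reference day.
#'
#' @param annotations output of [annotate_dynamics()].
#' @return data frame: axon_id, to_day, n_ref, formation_pct,
#'   elimination_pct.
#' @export
turnover_rates <- function(annotations) {
  key <- interaction(annotations$axon_id, annotations$to_day, drop = TRUE)
  rows <- lapply(split(annotations, key), function(g) {
    n_ref <- sum(g$state %in% c("persistent", "eliminated"))
    data.frame(
      axon_id = g$axon_id[1], to_day = g$to_day[1], n_ref = n_ref,
      formation_pct = if (n_ref > 0) 100 * sum(g$state == "formed") / n_ref
                      else NA_real_,
      elimination_pct = if (n_ref > 0)
        100 * sum(g$state == "eliminated") / n_ref else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$axon_id, out$to_day), ]
  rownames(out) <- NULL
  out
}

#' Survival of boutons formed on a given day
#'
#' The fraction of boutons formed on `formation_day` that are still present
#' on each later check day.
#'
#' @param track a `bouton_track`.
#' @param formation_day day on which the cohort formed (default 4).
#' @param check_days later days to evaluate (default 6, 8, 10).
#' @return named numeric vector of fractions, plus attribute `n_formed`.
#' @export
survival_curve <- function(track, formation_day = 4,
                           check_days = c(6, 8, 10)) {
  stop_if_not(formation_day %in% track$days &&
                all(check_days %in% track$days),
              "formation_day and check_days must be imaged days")
  d_idx <- match(formation_day, track$days)
  stop_if_not(d_idx > 1, "formation day cannot be the first imaged day")
  formed <- track$presence[, d_idx] & !track$presence[, d_idx - 1L]
  if (!any(formed)) stop("no boutons formed on day ", formation_day,
                         call. = FALSE)
  out <- vapply(check_days, function(d)
    mean(track$presence[formed, match(d, track$days)]), 0)
  names(out) <- paste0("day", check_days)
  attr(out, "n_formed") <- sum(formed)
  out
}

#' Pairwise distances between co-formed boutons
#'
#' Along-axon distances between all pairs of boutons formed on the same
#' axon on the same day.
#'
#' @param track a `bouton_track`.
#' @param day formation day.
#' @return numeric vector of distances (um); empty when no axon formed two
#'   or more boutons that day.
#' @export
new_bouton_pair_distances <- function(track, day) {
  d_idx <- match(day, track$days)
  stop_if_not(!is.na(d_idx) && d_idx > 1, "day must be a non-initial session")
  formed <- track$presence[, d_idx] & !track$presence[, d_idx - 1L]
  dists <- numeric(0)
  for (a in unique(track$boutons$axon_id[formed])) {
    pos <- track$boutons$position_um[formed & track$boutons$axon_id == a]
    if (length(pos) >= 2)
      dists <- c(dists, as.vector(stats::dist(pos)))
  }
  dists
}

#' Across-axon correlation of densities on two days
#'
#' @param densities output of [density_timecourse()].
#' @param day_a,day_b the two days.
#' @return Pearson r across axons.
#' @export
density_day_correlation <- function(densities, day_a, day_b) {
  da <- densities[densities$day == day_a, c("axon_id", "density")]
  db <- densities[densities$day == day_b, c("axon_id", "density")]
  m <- merge(da, db, by = "axon_id")
  stop_if_not(nrow(m) >= 3, "need at least 3 axons with both densities")
  stop_if_not(stats::sd(m$density.x) > 0 && stats::sd(m$density.y) > 0,
              "correlation undefined with zero variance")
  stats::cor(m$density.x, m$density.y)
}

#' Join structural dynamics with functional axon classes
#'
#' Stratifies per-axon formation rates by late-stage class, elimination
#' rates by early-stage class, and the relative density change
#' (last day / first day) by the early -> late class path. Axons missing a
#' class record are excluded.
#'
#' @param track a `bouton_track`.
#' @param axon_classes data frame: axon_id, early_class, late_class (using
#'   "RM" for RM-responsive, i.e. RM_only or both, and "UM" otherwise among
#'   responsive axons; any labels are accepted and used as given).
#' @return list of data frames: `formation_by_late`, `elimination_by_early`,
#'   `density_change_by_path`.
#' @export
function_structure_join <- function(track, axon_classes) {
  ann <- annotate_dynamics(track)
  rates <- turnover_rates(ann)
  per_axon_rate <- do.call(rbind, lapply(split(rates, rates$axon_id),
    function(g) data.frame(
      axon_id = g$axon_id[1],
      formation_pct = mean(g$formation_pct, na.rm = TRUE),
      elimination_pct = mean(g$elimination_pct, na.rm = TRUE))))
  dens <- density_timecourse(track)
  last_day <- max(track$days); first_day <- min(track$days)
  change <- do.call(rbind, lapply(split(dens, dens$axon_id), function(g)
    data.frame(axon_id = g$axon_id[1],
               density_change = g$density[g$day == last_day] /
                 max(g$density[g$day == first_day], .Machine$double.eps))))
  m <- merge(merge(per_axon_rate, change, by = "axon_id"),
             axon_classes, by = "axon_id")
  agg <- function(value, by) {
    out <- stats::aggregate(value, list(class = by),
                            function(v) c(mean = mean(v), n = length(v)))
    data.frame(class = out$class, mean = out$x[, "mean"], n = out$x[, "n"])
  }
  list(
    formation_by_late = agg(m$formation_pct, m$late_class),
    elimination_by_early = agg(m$elimination_pct, m$early_class),
    density_change_by_path = agg(m$density_change,
                                 paste(m$early_class, m$late_class,
                                       sep = "->"))
  )
}
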