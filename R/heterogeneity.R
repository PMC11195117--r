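#' Match calcium peaks between two boutons
#'
#' One-to-one matching of two sorted event trains: events within `tol`
#' seconds of each other (670 ms by default) are the "same peak"; events
#' with no partner are "unique peaks". Matching is greedy over the first
#' train's events in time order, pairing each with its nearest unmatched
#' partner in the second train within `tol`. For trains whose inter-event
#' spacing exceeds 2 * `tol` this equals the maximum-cardinality matching.
#'
#' @param times_i,times_j sorted event times (s) of the two boutons.
#' @param tol matching tolerance, s (default 0.670).
#' @return list of class `peak_match`: `matched` (2-column matrix of paired
#'   times), `unique_i`, `unique_j`, `n_i`, `n_j`.
#' @export
match_peaks <- function(times_i, times_j, tol = 0.670) {
  stop_if_not(!is.unsorted(times_i) && !is.unsorted(times_j),
              "event trains must be sorted")
  used_j <- rep(FALSE, length(times_j))
  mi <- integer(0); mj <- integer(0)
  for (i in seq_along(times_i)) {
    cand <- which(!used_j & abs(times_j - times_i[i]) <= tol)
    if (length(cand)) {
      j <- cand[which.min(abs(times_j[cand] - times_i[i]))]
      used_j[j] <- TRUE
      mi <- c(mi, i); mj <- c(mj, j)
    }
  }
  structure(list(
    matched = cbind(time_i = times_i[mi], time_j = times_j[mj]),
    unique_i = times_i[setdiff(seq_along(times_i), mi)],
    unique_j = times_j[which(!used_j)],
    n_i = length(times_i), n_j = length(times_j)
  ), class = "peak_match")
}

#' Same-peak fraction of a bouton pair
#'
#' A matched pair counts as one same peak in each bouton's tally, so the
#' fraction is `2 * matched / (n_i + n_j)`.
#'
#' @param match a `peak_match`.
#' @return fraction in 0..1.
#' @export
same_peak_fraction <- function(match) {
  total <- match$n_i + match$n_j
  stop_if_not(total > 0, "same-peak fraction undefined for two empty trains")
  2 * nrow(match$matched) / total
}

#' Hierarchical average of same-peak fractions
#'
#' Averages pair fractions per bouton (over the pairs it participates in),
#' then per axon (over its boutons), then over axons, giving one value per
#' mouse. Axons with fewer than two boutons carry no pairs and are excluded.
#'
#' @param pairs data frame with columns bouton_i, bouton_j, axon_id,
#'   fraction (one row per same-axon bouton pair).
#' @return list: `mouse` (scalar), `per_axon` (named vector),
#'   `per_bouton` (data frame bouton_id, axon_id, mean_fraction).
#' @export
aggregate_same_fraction <- function(pairs) {
  stop_if_not(nrow(pairs) > 0, "no bouton pairs")
  boutons <- unique(data.frame(
    bouton_id = c(pairs$bouton_i, pairs$bouton_j),
    axon_id = c(pairs$axon_id, pairs$axon_id)))
  per_bouton <- vapply(seq_len(nrow(boutons)), function(r) {
    b <- boutons$bouton_id[r]
    mean(pairs$fraction[pairs$bouton_i == b | pairs$bouton_j == b])
  }, 0)
  boutons$mean_fraction <- per_bouton
  per_axon <- tapply(boutons$mean_fraction, boutons$axon_id, mean)
  per_axon <- stats::setNames(as.vector(per_axon), names(per_axon))
  list(mouse = mean(per_axon), per_axon = per_axon, per_bouton = boutons)
}

#' Same-peak fractions for all same-axon bouton pairs
#'
#' @param events event table (bouton_id, axon_id, time_s), e.g. from
#'   [detect_events_all()].
#' @param tol matching tolerance, s.
#' @return data frame: axon_id, bouton_i, bouton_j, n_matched, n_i, n_j,
#'   fraction. Pairs where both trains are empty are skipped.
#' @export
same_axon_pair_fractions <- function(events, tol = 0.670) {
  rows <- list()
  for (a in unique(events$axon_id)) {
    b_ids <- sort(unique(events$bouton_id[events$axon_id == a]))
    if (length(b_ids) < 2) next
    for (i in seq_along(b_ids)[-length(b_ids)]) {
      for (j in (i + 1):length(b_ids)) {
        ti <- sort(events$time_s[events$bouton_id == b_ids[i]])
        tj <- sort(events$time_s[events$bouton_id == b_ids[j]])
        if (length(ti) + length(tj) == 0) next
        m <- match_peaks(ti, tj, tol)
        rows[[length(rows) + 1L]] <- data.frame(
          axon_id = a, bouton_i = b_ids[i], bouton_j = b_ids[j],
          n_matched = nrow(m$matched), n_i = m$n_i, n_j = m$n_j,
          fraction = same_peak_fraction(m))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(axon_id = integer(0), bouton_i = integer(0),
                      bouton_j = integer(0), n_matched = integer(0),
                      n_i = integer(0), n_j = integer(0),
                      fraction = numeric(0))
  out
}

#' Associate a peak with a movement outcome
#'
#' A peak is RM- (UM-) related when it falls inside the window 330 ms
#' before to 670 ms after an RM (UM) onset. When windows of both outcomes
#' cover the peak, the nearest onset wins.
#'
#' @param peak_times peak times, s.
#' @param bouts labeled bout data frame (onset, label).
#' @param window window (s) relative to onset, default c(-0.33, 0.67).
#' @return character vector "RM" / "UM" / "none" per peak.
#' @export
label_peak_outcome <- function(peak_times, bouts, window = c(-0.33, 0.67)) {
  vapply(peak_times, function(tp) {
    hit <- which(tp >= bouts$onset + window[1] &
                   tp <= bouts$onset + window[2])
    if (!length(hit)) return("none")
    bouts$label[hit[which.min(abs(bouts$onset[hit] - tp))]]
  }, "")
}

#' Outcome-resolved same vs unique peak fractions
#'
#' Pools the matched and unique peaks of all same-axon bouton pairs, labels
#' each by outcome, and reports, among RM-related peaks, the fractions that
#' are same vs unique (summing to 1), and likewise for UM.
#'
#' @param events event table (bouton_id, axon_id, time_s).
#' @param bouts labeled bout data frame.
#' @param tol matching tolerance, s.
#' @param window outcome-association window, s.
#' @return data frame: outcome, same, unique, n (NA fractions when an
#'   outcome has no peaks).
#' @export
outcome_peak_fractions <- function(events, bouts, tol = 0.670,
                                   window = c(-0.33, 0.67)) {
  same_t <- numeric(0); uniq_t <- numeric(0)
  for (a in unique(events$axon_id)) {
    b_ids <- sort(unique(events$bouton_id[events$axon_id == a]))
    if (length(b_ids) < 2) next
    for (i in seq_along(b_ids)[-length(b_ids)]) {
      for (j in (i + 1):length(b_ids)) {
        ti <- sort(events$time_s[events$bouton_id == b_ids[i]])
        tj <- sort(events$time_s[events$bouton_id == b_ids[j]])
        m <- match_peaks(ti, tj, tol)
        if (nrow(m$matched))
          same_t <- c(same_t, rowMeans(m$matched))
        uniq_t <- c(uniq_t, m$unique_i, m$unique_j)
      }
    }
  }
  out <- lapply(c("RM", "UM"), function(lab) {
    n_same <- sum(label_peak_outcome(same_t, bouts, window) == lab)
    n_uniq <- sum(label_peak_outcome(uniq_t, bouts, window) == lab)
    n <- n_same + n_uniq
    data.frame(outcome = lab,
               same = if (n > 0) n_same / n else NA_real_,
               unique = if (n > 0) n_uniq / n else NA_real_,
               n = n)
  })
  do.call(rbind, out)
}

#' Axon activity heterogeneity
#'
#' The fraction of the minority outcome class among the RM- and UM-selective
#' boutons on one axon: 0 for a uniformly selective axon, 0.5 for a
#' maximally mixed one. Boutons classed "both" or "none" do not enter.
#'
#' @param classes character classes of the axon's boutons.
#' @return fraction in 0..0.5, or NA when fewer than two boutons are RM- or
#'   UM-selective.
#' @export
axon_heterogeneity <- function(classes) {
  sel <- classes[classes %in% c("RM_only", "UM_only")]
  if (length(sel) < 2) return(NA_real_)
  min(sum(sel == "RM_only"), sum(sel == "UM_only")) / length(sel)
}
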