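#' Simulate longitudinal bouton structure
#'
#' Generates per-axon bouton inventories across imaging days. Each axon
#' starts with boutons placed uniformly at `baseline_density`; across each
#' inter-session interval every present bouton is eliminated with probability
#' `elimination_rate`, and new boutons form in number
#' `Binomial(n_present, formation_rate)`. When `cluster_scale_um` is finite,
#' a new bouton is placed a Gaussian offset (sd = `cluster_scale_um`) from a
#' randomly chosen existing or co-formed bouton, reflected into the axon;
#' otherwise positions are uniform. Eliminated boutons stay absent.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `track` (a `bouton_track`) and `truth` (the structural
#'   event log: bouton_id, axon_id, day, type formed/eliminated).
#' @export
simulate_structure <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  days <- config$days
  n_days <- length(days)
  L <- config$axon_length_um

  boutons <- list()   # per-bouton meta rows
  presence <- list()  # per-bouton logical vectors over days
  log <- list()
  next_id <- 1L

  for (a in seq_len(config$n_axons)) {
    n0 <- max(1L, round(config$baseline_density * L))
    pos <- sort(stats::runif(n0, 0, L))
    ids <- seq.int(next_id, length.out = n0)
    next_id <- next_id + n0
    pres <- matrix(FALSE, n0, n_days)
    pres[, 1] <- TRUE
    meta <- data.frame(bouton_id = ids, axon_id = a, position_um = pos)

    for (d in 2:n_days) {
      alive_prev <- which(pres[, d - 1])
      # eliminations
      gone <- alive_prev[stats::runif(length(alive_prev)) <
                           config$elimination_rate]
      stay <- setdiff(alive_prev, gone)
      pres[stay, d] <- TRUE
      for (g in gone)
        log[[length(log) + 1L]] <- data.frame(
          bouton_id = meta$bouton_id[g], axon_id = a, day = days[d],
          type = "eliminated")
      # formations
      n_new <- stats::rbinom(1L, length(alive_prev), config$formation_rate)
      if (n_new > 0) {
        new_pos <- numeric(n_new)
        anchor_pool <- meta$position_um[alive_prev]
        for (k in seq_len(n_new)) {
          if (is.finite(config$cluster_scale_um) && length(anchor_pool)) {
            anchor <- sample(anchor_pool, 1L)
            p <- anchor + stats::rnorm(1, 0, config$cluster_scale_um)
            p <- abs(p)                       # reflect at 0
            if (p > L) p <- 2 * L - p         # reflect at L
            new_pos[k] <- min(max(p, 0), L)
          } else {
            new_pos[k] <- stats::runif(1, 0, L)
          }
          anchor_pool <- c(anchor_pool, new_pos[k])
        }
        new_ids <- seq.int(next_id, length.out = n_new)
        next_id <- next_id + n_new
        meta <- rbind(meta, data.frame(bouton_id = new_ids, axon_id = a,
                                       position_um = new_pos))
        grow <- matrix(FALSE, n_new, n_days)
        grow[, d] <- TRUE
        pres <- rbind(pres, grow)
        # new boutons persist forward subject to later elimination
        for (nid in new_ids)
          log[[length(log) + 1L]] <- data.frame(
            bouton_id = nid, axon_id = a, day = days[d], type = "formed")
      }
    }
    boutons[[a]] <- meta
    presence[[a]] <- pres
  }

  meta <- do.call(rbind, boutons)
  pres <- do.call(rbind, presence)
  rownames(meta) <- NULL
  colnames(pres) <- paste0("day", days)

  truth <- if (length(log)) do.call(rbind, log) else
    data.frame(bouton_id = integer(0), axon_id = integer(0),
               day = numeric(0), type = character(0))
  rownames(truth) <- NULL

  track <- structure(list(
    axons = data.frame(axon_id = seq_len(config$n_axons), length_um = L,
                       group = config$group),
    boutons = meta, presence = pres, days = days
  ), class = "bouton_track")

  list(track = track, truth = truth)
}

#' @export
print.bouton_track <- function(x, ...) {
  cat("<bouton_track>", nrow(x$axons), "axons,", nrow(x$boutons),
      "boutons over days", paste(x$days, collapse = ","), "\n")
  invisible(x)
}
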