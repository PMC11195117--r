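# Tabular I/O. All tables are TSV: UTF-8, LF, '.' decimal, header row.

#' Write a table as TSV
#' @param x data frame.
#' @param path output file.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a TSV table
#' @param path file written by [write_tsv_table()].
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a lever session to disk
#'
#' The trace goes to `<stem>_trace.tsv` (time_s, position_mm), the metadata
#' and cue onsets to `<stem>_meta.yaml`, ground-truth bouts (when present)
#' to `<stem>_truth.tsv`.
#'
#' @param session a `lever_session`.
#' @param stem path stem (no extension).
#' @export
write_lever_session <- function(session, stem) {
  n <- length(session$positions)
  write_tsv_table(data.frame(
    time_s = (seq_len(n) - 1) / session$sample_rate,
    position_mm = session$positions), paste0(stem, "_trace.tsv"))
  yaml::write_yaml(list(
    sample_rate = session$sample_rate, cue_onsets = session$cue_onsets,
    task_period = session$task_period,
    push_threshold = session$push_threshold,
    iti_duration = session$iti_duration, duration = session$duration
  ), paste0(stem, "_meta.yaml"))
  if (nrow(session$truth))
    write_tsv_table(session$truth, paste0(stem, "_truth.tsv"))
  invisible(stem)
}

#' Read a lever session written by [write_lever_session()]
#' @param stem path stem used when writing.
#' @return a `lever_session`.
#' @export
read_lever_session <- function(stem) {
  tr <- read_tsv_table(paste0(stem, "_trace.tsv"))
  meta <- yaml::read_yaml(paste0(stem, "_meta.yaml"))
  truth_path <- paste0(stem, "_truth.tsv")
  truth <- if (file.exists(truth_path)) read_tsv_table(truth_path) else
    data.frame(onset = numeric(0), offset = numeric(0), peak_mm = numeric(0),
               label = character(0), during_iti = logical(0))
  structure(list(
    positions = tr$position_mm, sample_rate = meta$sample_rate,
    cue_onsets = as.numeric(unlist(meta$cue_onsets)),
    task_period = meta$task_period, push_threshold = meta$push_threshold,
    iti_duration = meta$iti_duration, duration = meta$duration,
    truth = truth
  ), class = "lever_session")
}

#' Write a fluorescence set as wide TSV (frames x boutons)
#' @param fluor a `fluor_set`.
#' @param stem path stem.
#' @export
write_fluor_set <- function(fluor, stem) {
  wide <- as.data.frame(t(fluor$raw))
  names(wide) <- paste0("bouton_", fluor$bouton_ids)
  write_tsv_table(wide, paste0(stem, "_raw.tsv"))
  write_tsv_table(data.frame(bouton_id = fluor$bouton_ids,
                             axon_id = fluor$axon_of),
                  paste0(stem, "_map.tsv"))
  yaml::write_yaml(list(frame_rate = fluor$frame_rate, day = fluor$day),
                   paste0(stem, "_meta.yaml"))
  invisible(stem)
}

#' Read a fluorescence set written by [write_fluor_set()]
#' @param stem path stem.
#' @return a `fluor_set`.
#' @export
read_fluor_set <- function(stem) {
  wide <- read_tsv_table(paste0(stem, "_raw.tsv"))
  map <- read_tsv_table(paste0(stem, "_map.tsv"))
  meta <- yaml::read_yaml(paste0(stem, "_meta.yaml"))
  structure(list(
    raw = t(as.matrix(wide)), frame_rate = meta$frame_rate,
    bouton_ids = map$bouton_id, axon_of = map$axon_id,
    day = meta$day %||% NA_integer_
  ), class = "fluor_set")
}

#' Write a bouton track as long TSV
#'
#' One row per bouton per day: axon_id, bouton_id, position_um, day,
#' present; axon metadata in a companion `<stem>_axons.tsv`.
#'
#' @param track a `bouton_track`.
#' @param stem path stem.
#' @export
write_bouton_track <- function(track, stem) {
  long <- do.call(rbind, lapply(seq_along(track$days), function(d)
    data.frame(axon_id = track$boutons$axon_id,
               bouton_id = track$boutons$bouton_id,
               position_um = track$boutons$position_um,
               day = track$days[d], present = track$presence[, d])))
  write_tsv_table(long, paste0(stem, "_track.tsv"))
  write_tsv_table(track$axons, paste0(stem, "_axons.tsv"))
  invisible(stem)
}

#' Read a bouton track written by [write_bouton_track()]
#' @param stem path stem.
#' @return a `bouton_track`.
#' @export
read_bouton_track <- function(stem) {
  long <- read_tsv_table(paste0(stem, "_track.tsv"))
  axons <- read_tsv_table(paste0(stem, "_axons.tsv"))
  days <- as.numeric(sort(unique(long$day)))
  b <- unique(long[, c("axon_id", "bouton_id", "position_um")])
  b <- b[order(b$bouton_id), ]
  rownames(b) <- NULL
  pres <- vapply(days, function(d) {
    g <- long[long$day == d, ]
    g$present[match(b$bouton_id, g$bouton_id)]
  }, logical(nrow(b)))
  pres <- matrix(pres, nrow = nrow(b))
  colnames(pres) <- paste0("day", days)
  structure(list(axons = axons, boutons = b, presence = pres, days = days),
            class = "bouton_track")
}
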