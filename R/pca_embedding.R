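#' Concatenated trial-averaged activity matrix
#'
#' Stacks, per bouton, the trial-averaged RM activity on top of the
#' trial-averaged UM activity, giving a 2M-by-N matrix (M = frames per
#' trial window, N = boutons). Boutons missing either trial type are
#' excluded and reported.
#'
#' @param tensor a `trial_tensor` containing both RM and UM trials.
#' @return list: `matrix` (2M x N), `boutons` (column -> bouton index),
#'   `excluded` (bouton indices lacking a trial type), `m` (frames per half).
#' @export
build_concat_matrix <- function(tensor) {
  n_b <- dim(tensor$activity)[1]
  m <- dim(tensor$activity)[3]
  cols <- list(); kept <- integer(0); excluded <- integer(0)
  for (b in seq_len(n_b)) {
    rm_avg <- trial_average(tensor, b, "RM")
    um_avg <- trial_average(tensor, b, "UM")
    if (is.null(rm_avg) || is.null(um_avg)) {
      excluded <- c(excluded, b)
    } else {
      kept <- c(kept, b)
      cols[[length(cols) + 1L]] <- c(rm_avg, um_avg)
    }
  }
  stop_if_not(length(kept) > 0, "no bouton has both RM and UM trials")
  list(matrix = do.call(cbind, cols), boutons = kept, excluded = excluded,
       m = m)
}

# fix the sign of each component so the largest-|.| loading is positive
fix_signs <- function(loadings, scores) {
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' PCA embedding of boutons from concatenated trial averages
#'
#' Performs PCA across the time points of the concatenated RM+UM
#' trial-averaged matrix (each bouton's column is mean-centered; no variance
#' scaling) and returns each bouton's coordinates on the first `k`
#' components, so each bouton is one dot in PC space.
#'
#' @param concat output of [build_concat_matrix()] (or a bare 2M x N matrix).
#' @param k number of components (default 3).
#' @return list: `scores` (N x k bouton coordinates), `loadings` (2M x k
#'   time-course loadings), `explained` (variance ratios, non-increasing),
#'   `boutons`.
#' @export
embed_boutons <- function(concat, k = 3) {
  x <- if (is.list(concat)) concat$matrix else concat
  boutons <- if (is.list(concat)) concat$boutons else seq_len(ncol(x))
  stop_if_not(ncol(x) >= k, "need at least k boutons")
  xc <- sweep(x, 2, colMeans(x))  # center each bouton's profile
  sv <- svd(xc)
  r <- sum(sv$d > max(dim(xc)) * max(sv$d) * .Machine$double.eps)
  if (r < k) {
    warning("rank-deficient input: returning ", r, " components")
    k <- r
  }
  loadings <- sv$u[, seq_len(k), drop = FALSE]     # time-point directions
  scores <- sv$v[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)                   # bouton coordinates
  fs <- fix_signs(loadings, scores)
  explained <- sv$d^2 / sum(sv$d^2)
  list(scores = fs$scores, loadings = fs$loadings,
       explained = explained[seq_len(k)], boutons = boutons)
}

#' Population PC time courses of a continuous imaged segment
#'
#' PCA of the boutons-by-frames dF/F matrix of one continuous segment
#' (boutons as variables, mean-centered, unscaled); returns the first `k`
#' population components as time series.
#'
#' @param dff_segment boutons-by-frames dF/F matrix.
#' @param k number of components (default 3).
#' @return list: `pcs` (frames x k PC time courses), `loadings`
#'   (boutons x k), `explained` (variance ratios).
#' @export
segment_pca <- function(dff_segment, k = 3) {
  stop_if_not(is.matrix(dff_segment), "dff_segment must be a matrix")
  n_b <- nrow(dff_segment)
  if (n_b < k) {
    warning("fewer boutons than components: reducing k to ", n_b)
    k <- n_b
  }
  x <- t(dff_segment)                      # frames x boutons
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = k, nv = k)
  loadings <- sv$v
  pcs <- x %*% loadings
  fs <- fix_signs(loadings, pcs)
  explained <- sv$d^2 / sum(sv$d^2)
  list(pcs = fs$scores, loadings = fs$loadings, explained = explained[1:k])
}

#' Extract single-trial PC-space trajectories
#'
#' Aligns the PC time courses to each movement onset over the trial window
#' and returns per-trial k-dimensional trajectories plus the mean RM and UM
#' trajectories (frame-wise averages of their member trials).
#'
#' @param pcs frames x k PC time courses ([segment_pca()]).
#' @param onsets movement onsets, s.
#' @param labels trial labels ("RM"/"UM").
#' @param frame_rate Hz.
#' @param window trial window in s relative to onset (default c(-1, 3)).
#' @return a `trajectory_set`: `trials` (list of frames x k matrices),
#'   `labels`, `mean_rm`, `mean_um` (NULL when that label has no trials),
#'   `time`.
#' @export
extract_trajectories <- function(pcs, onsets, labels, frame_rate,
                                 window = c(-1, 3)) {
  stop_if_not(length(onsets) == length(labels),
              "onsets and labels must have equal length")
  pre <- round(-window[1] * frame_rate)
  post <- round(window[2] * frame_rate)
  len <- pre + post + 1L
  onset_frame <- round(onsets * frame_rate) + 1L
  ok <- onset_frame - pre >= 1L & onset_frame + post <= nrow(pcs)
  trials <- lapply(which(ok), function(i) {
    i0 <- onset_frame[i] - pre
    pcs[i0:(i0 + len - 1L), , drop = FALSE]
  })
  labels <- labels[ok]
  mean_traj <- function(lab) {
    sel <- which(labels == lab)
    if (!length(sel)) return(NULL)
    Reduce(`+`, trials[sel]) / length(sel)
  }
  structure(list(
    trials = trials, labels = labels,
    mean_rm = mean_traj("RM"), mean_um = mean_traj("UM"),
    time = (seq_len(len) - 1L - pre) / frame_rate
  ), class = "trajectory_set")
}

#' Trajectory selectivity index of a single trial
#'
#' Frame-by-frame, let d_RM and d_UM be the Euclidean distances from the
#' single-trial PC trajectory to the mean RM and mean UM trajectories. For
#' an RM trial the index is `(d_UM - d_RM) / (d_RM + d_UM)`; for a UM trial
#' the roles swap: `(d_RM - d_UM) / (d_RM + d_UM)`. The index is +1 when the
#' trial sits exactly on its own type's mean trajectory (and away from the
#' other), -1 when it sits on the opposite mean. Frames where both
#' distances are zero are undefined and excluded.
#'
#' @param trial_traj frames x k single-trial trajectory.
#' @param mean_rm,mean_um mean trajectories (same shape).
#' @param label "RM" or "UM".
#' @return list: `index` per-frame values (NA where undefined), `trial_mean`
#'   average over defined frames.
#' @export
selectivity_index <- function(trial_traj, mean_rm, mean_um, label) {
  stop_if_not(label %in% c("RM", "UM"), "label must be 'RM' or 'UM'")
  stop_if_not(all(dim(trial_traj) == dim(mean_rm)) &&
                all(dim(trial_traj) == dim(mean_um)),
              "trajectories must share dimensions")
  d_rm <- sqrt(rowSums((trial_traj - mean_rm)^2))
  d_um <- sqrt(rowSums((trial_traj - mean_um)^2))
  denom <- d_rm + d_um
  idx <- ifelse(denom > 0,
                if (label == "RM") (d_um - d_rm) / denom
                else (d_rm - d_um) / denom,
                NA_real_)
  if (all(is.na(idx)))
    stop("selectivity undefined: trial coincides with both means everywhere",
         call. = FALSE)
  list(index = idx, trial_mean = mean(idx, na.rm = TRUE))
}

#' Selectivity indices for every trial of a trajectory set
#'
#' @param traj a `trajectory_set` with both mean trajectories defined.
#' @return data frame: trial, label, selectivity (trial mean).
#' @export
selectivity_indices <- function(traj) {
  stop_if_not(!is.null(traj$mean_rm) && !is.null(traj$mean_um),
              "both RM and UM mean trajectories are required")
  data.frame(
    trial = seq_along(traj$trials),
    label = traj$labels,
    selectivity = vapply(seq_along(traj$trials), function(i)
      selectivity_index(traj$trials[[i]], traj$mean_rm, traj$mean_um,
                        traj$labels[i])$trial_mean, 0)
  )
}
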