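#' Link single-molecule localizations into tracks
#'
#' Frame-to-frame linking: for every pair of consecutive frames, open track
#' ends are matched to the next frame's localizations by minimizing the total
#' displacement (optimal linear assignment), with a hard gate — pairs farther
#' apart than \code{max_displacement} are never linked, and the objective
#' charges \code{max_displacement} for each unmatched end or localization, so
#' every link within the gate is preferred over leaving both sides
#' unmatched. A track ends when it finds no partner (no gap closing: a missed
#' frame terminates the track), and unmatched localizations start new tracks.
#' Tracks shorter than \code{min_track_length} localizations are discarded.
#'
#' @param localizations Data frame with columns \code{frame}, \code{x_um},
#'   \code{y_um}, sorted by frame (any \code{molecule_id} column is ignored —
#'   identity must be recovered by the linker).
#' @param max_displacement Gate distance, \eqn{\mu m}. The default 0.5
#'   corresponds to about 5 SD of a single-axis step at the mobility
#'   threshold of 0.15 um^2/s and 15.26 ms frame interval.
#' @param min_track_length Minimum retained track length in localizations
#'   (default 5).
#' @return Data frame with columns \code{track_id}, \code{frame},
#'   \code{x_um}, \code{y_um}; consecutive frames within a track differ by 1.
#'   Empty input gives an empty result.
#' @export
link_tracks <- function(localizations, max_displacement = 0.5,
                        min_track_length = 5) {
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0))
  if (is.null(localizations) || nrow(localizations) == 0) return(empty)
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(localizations)),
            max_displacement > 0, min_track_length >= 1)
  loc <- localizations[order(localizations$frame), , drop = FALSE]
  frames <- sort(unique(loc$frame))
  by_frame <- split(seq_len(nrow(loc)), loc$frame)

  track_of <- integer(nrow(loc))   # track id per localization
  next_id <- 0L
  # open tracks: localization row index of each track's last point
  open_rows <- integer(0)

  for (fi in seq_along(frames)) {
    rows <- by_frame[[as.character(frames[fi])]]
    prev_frame_ok <- fi > 1 && frames[fi] - frames[fi - 1] == 1
    if (!prev_frame_ok || length(open_rows) == 0) {
      # all localizations start new tracks; previously open tracks terminate
      for (r in rows) {
        next_id <- next_id + 1L
        track_of[r] <- next_id
      }
      open_rows <- rows
      next
    }
    n_open <- length(open_rows)
    n_new <- length(rows)
    dmat <- sqrt(outer(loc$x_um[open_rows], loc$x_um[rows], "-")^2 +
                 outer(loc$y_um[open_rows], loc$y_um[rows], "-")^2)
    # pad to square: unmatched track end / new localization costs the gate
    n <- n_open + n_new
    big <- 1e9
    cost <- matrix(0, n, n)
    link_cost <- dmat
    link_cost[dmat > max_displacement] <- big
    cost[seq_len(n_open), seq_len(n_new)] <- link_cost
    cost[seq_len(n_open), n_new + seq_len(n_open)] <-
      `diag<-`(matrix(big, n_open, n_open), max_displacement)
    cost[n_open + seq_len(n_new), seq_len(n_new)] <-
      `diag<-`(matrix(big, n_new, n_new), max_displacement)
    cost[n_open + seq_len(n_new), n_new + seq_len(n_open)] <- 0
    assign <- solve_assignment(cost)
    new_open <- integer(0)
    matched_new <- logical(n_new)
    for (k in seq_len(n_open)) {
      j <- assign[k]
      if (j <= n_new && link_cost[k, j] < big) {
        r <- rows[j]
        track_of[r] <- track_of[open_rows[k]]
        matched_new[j] <- TRUE
        new_open <- c(new_open, r)
      }
    }
    for (j in which(!matched_new)) {
      next_id <- next_id + 1L
      track_of[rows[j]] <- next_id
      new_open <- c(new_open, rows[j])
    }
    open_rows <- new_open
  }

  loc$track_id <- track_of
  keep_ids <- names(which(table(loc$track_id) >= min_track_length))
  out <- loc[loc$track_id %in% as.integer(keep_ids),
             c("track_id", "frame", "x_um", "y_um")]
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  # renumber retained tracks consecutively
  out$track_id <- match(out$track_id, unique(out$track_id))
  rownames(out) <- NULL
  out
}

#' Single-step diffusion coefficient of a track
#'
#' The mean over consecutive steps of \eqn{(\Delta x^2 + \Delta y^2) /
#' (4 \Delta t)}. For Brownian motion with Gaussian localization error of SD
#' \eqn{\sigma_{loc}} per axis, its expectation is \eqn{D +
#' \sigma_{loc}^2/\Delta t}; no error correction is applied, matching the
#' classification convention, but the bias should be kept in mind when
#' choosing thresholds.
#'
#' @param track Data frame with columns \code{frame}, \code{x_um},
#'   \code{y_um}; consecutive frames, at least 2 localizations.
#' @param frame_interval Frame interval, s (default 15.26 ms).
#' @return D*, \eqn{\mu m^2/s}.
#' @export
single_step_D <- function(track, frame_interval = 0.01526) {
  stopifnot(nrow(track) >= 2, frame_interval > 0)
  dx <- diff(track$x_um)
  dy <- diff(track$y_um)
  mean(dx^2 + dy^2) / (4 * frame_interval)
}

#' Classify tracks as bound or mobile
#'
#' Computes the per-track single-step diffusion coefficient and labels a
#' track \code{mobile} when D* strictly exceeds the threshold (a track
#' exactly at the threshold is bound). Also pools per-step instantaneous
#' coefficients across tracks for step-wise histograms.
#'
#' @param tracks Data frame from \code{\link{link_tracks}} (columns
#'   \code{track_id}, \code{frame}, \code{x_um}, \code{y_um}).
#' @param threshold Mobility threshold on D*, \eqn{\mu m^2/s} (default 0.15).
#' @param frame_interval Frame interval, s.
#' @return Object of class \code{mobility_summary}: \code{n_tracks},
#'   \code{mobile_fraction}, \code{per_track} (data frame \code{track_id},
#'   \code{length}, \code{D_star}, \code{label}), \code{bound_positions}
#'   (mean (x, y) of each bound track), \code{step_D} (pooled per-step
#'   coefficients), \code{threshold}, \code{frame_interval}.
#' @export
classify_mobility <- function(tracks, threshold = 0.15,
                              frame_interval = 0.01526) {
  stopifnot(nrow(tracks) >= 1,
            all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  split_tracks <- split(tracks, tracks$track_id)
  d_star <- vapply(split_tracks, single_step_D, 0,
                   frame_interval = frame_interval)
  lens <- vapply(split_tracks, nrow, 0L)
  label <- ifelse(d_star > threshold, "mobile", "bound")
  per_track <- data.frame(track_id = as.integer(names(split_tracks)),
                          length = lens, D_star = d_star, label = label,
                          row.names = NULL)
  bound <- split_tracks[label == "bound"]
  bound_positions <- if (length(bound))
    data.frame(x_um = vapply(bound, function(tr) mean(tr$x_um), 0),
               y_um = vapply(bound, function(tr) mean(tr$y_um), 0),
               row.names = NULL)
  else data.frame(x_um = numeric(0), y_um = numeric(0))
  step_D <- unlist(lapply(split_tracks, function(tr)
    (diff(tr$x_um)^2 + diff(tr$y_um)^2) / (4 * frame_interval)),
    use.names = FALSE)
  structure(
    list(n_tracks = length(split_tracks),
         mobile_fraction = mean(label == "mobile"),
         per_track = per_track, bound_positions = bound_positions,
         step_D = step_D, threshold = threshold,
         frame_interval = frame_interval),
    class = "mobility_summary"
  )
}

#' @export
print.mobility_summary <- function(x, ...) {
  cat(sprintf(
    "Mobility: %d tracks, %.1f%% mobile (D* > %.2f um^2/s at dt = %.5f s)\n",
    x$n_tracks, 100 * x$mobile_fraction, x$threshold, x$frame_interval))
  invisible(x)
}

#' @export
plot.mobility_summary <- function(x, breaks = 40, ...) {
  hist(x$per_track$D_star, breaks = breaks,
       xlab = expression(D * "*" ~ (mu * m^2 / s)),
       main = "Per-track single-step diffusion coefficients", ...)
  abline(v = x$threshold, col = "firebrick", lwd = 2, lty = 2)
  invisible(x)
}
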