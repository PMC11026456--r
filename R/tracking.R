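# Proximity-based centroid linking and accumulated-distance velocities.

#' Link per-frame centroids into trajectories by proximity
#'
#' Greedy mutually-nearest-pair assignment per frame transition: the globally
#' closest (track end, next-frame centroid) pair is linked first, then the
#' next closest among the remainder, and so on; ties break toward the
#' smaller track id. Links longer than `max_link_distance` are not made —
#' the unmatched centroid starts a new trajectory. Trajectories do not
#' bridge missed frames. Exactly coincident centroids within one frame are
#' accepted and flagged.
#'
#' @param centroids data frame with columns `frame`, `x_um`, `y_um` (frames
#'   need not be consecutive but are processed in increasing order).
#' @param max_link_distance largest allowed frame-to-frame step in um.
#' @return list of trajectory data frames (`track_id`, `frame`, `x_um`,
#'   `y_um`); attribute `duplicate_frames` lists frames containing
#'   coincident centroids.
#' @export
link_centroids <- function(centroids, max_link_distance = 30) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(centroids)))
  frames <- sort(unique(centroids$frame))
  if (length(frames) < 2) stop("need centroids from >= 2 frames")
  dup_frames <- integer(0)
  per_frame <- lapply(frames, function(f) {
    m <- as.matrix(centroids[centroids$frame == f, c("x_um", "y_um")])
    if (anyDuplicated(m)) dup_frames <<- c(dup_frames, f)
    m
  })
  tracks <- list()        # each: list(frames =, xy = matrix)
  active <- integer(0)    # indices into `tracks` still extendable
  pts <- per_frame[[1]]
  for (p in seq_len(nrow(pts))) {
    tracks[[p]] <- list(frames = frames[1], xy = pts[p, , drop = FALSE])
    active <- c(active, p)
  }
  for (fi in 2:length(frames)) {
    pts <- per_frame[[fi]]
    n_new <- nrow(pts)
    linked_new <- logical(n_new)
    if (length(active) > 0 && n_new > 0) {
      ends <- t(vapply(active, function(t)
        tracks[[t]]$xy[nrow(tracks[[t]]$xy), ], numeric(2)))
      D <- outer(seq_len(nrow(ends)), seq_len(n_new), function(a, b)
        sqrt((ends[a, 1] - pts[b, 1])^2 + (ends[a, 2] - pts[b, 2])^2))
      D <- matrix(D, nrow(ends), n_new)
      open_t <- rep(TRUE, nrow(ends)); open_p <- rep(TRUE, n_new)
      repeat {
        Dm <- D
        Dm[!open_t, ] <- Inf; Dm[, !open_p] <- Inf
        dmin <- min(Dm)
        if (!is.finite(dmin) || dmin > max_link_distance) break
        hit <- which(Dm == dmin, arr.ind = TRUE)
        # tie-break: smallest track id, then smallest point index
        hit <- hit[order(active[hit[, 1]], hit[, 2]), , drop = FALSE][1, ]
        ti <- hit[1]; pj <- hit[2]
        tr <- active[ti]
        tracks[[tr]]$frames <- c(tracks[[tr]]$frames, frames[fi])
        tracks[[tr]]$xy <- rbind(tracks[[tr]]$xy, pts[pj, ])
        open_t[ti] <- FALSE; open_p[pj] <- FALSE
        linked_new[pj] <- TRUE
      }
      active <- active[!open_t]  # tracks not extended stop here
    } else active <- integer(0)
    for (p in which(!linked_new)) {
      tracks[[length(tracks) + 1]] <- list(frames = frames[fi],
                                           xy = pts[p, , drop = FALSE])
      active <- c(active, length(tracks))
    }
  }
  out <- lapply(seq_along(tracks), function(i) {
    data.frame(track_id = i, frame = tracks[[i]]$frames,
               x_um = tracks[[i]]$xy[, 1], y_um = tracks[[i]]$xy[, 2])
  })
  attr(out, "duplicate_frames") <- unique(dup_frames)
  out
}

#' Migration velocity of a trajectory
#'
#' Accumulated path length divided by the total elapsed time:
#' `sum(consecutive Euclidean steps) / ((frame span) * frame_interval)`.
#' A circular path therefore has positive velocity (accumulated, not net,
#' displacement). Single-point trajectories return `NA`.
#'
#' @param track trajectory data frame with `frame`, `x_um`, `y_um`.
#' @param frame_interval time between consecutive frames in minutes.
#' @return velocity in um/min (`NA` for a single-point trajectory).
#' @export
velocity <- function(track, frame_interval) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (n < 2) return(NA_real_)
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  span <- track$frame[n] - track$frame[1]
  sum(steps) / (span * frame_interval)
}

#' Per-track velocity summary
#'
#' Applies [velocity()] to every trajectory; trajectories shorter than
#' `min_frames` are flagged (`included = FALSE`) and excluded from summary
#' statistics, replacing the manual discarding of unreliable tracks with an
#' explicit rule.
#'
#' @param tracks list of trajectories from [link_centroids()].
#' @param frame_interval minutes between frames.
#' @param min_frames minimum trajectory length for inclusion (default 5).
#' @return data frame: track_id, n_frames, velocity_um_min, included.
#' @export
track_velocities <- function(tracks, frame_interval, min_frames = 5) {
  data.frame(
    track_id = vapply(tracks, function(t) t$track_id[1], numeric(1)),
    n_frames = vapply(tracks, nrow, numeric(1)),
    velocity_um_min = vapply(tracks, velocity, numeric(1),
                             frame_interval = frame_interval),
    included = vapply(tracks, nrow, numeric(1)) >= min_frames)
}
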