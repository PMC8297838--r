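# Bout segmentation: a speed-threshold state machine over smoothed per-frame
# speeds. Frames at or below the resting speed are stationary; maximal
# supra-threshold runs become candidate movement bouts, and candidates whose
# path length does not exceed the minimum movement length are treated as
# tracking noise and absorbed into the surrounding rest, so the bout sequence
# always partitions the whole recording.

#' Smoothed per-frame speeds
#'
#' Speed at frame i is the path length accumulated inside a centred window of
#' width `window` seconds divided by the actual window duration; windows are
#' truncated at the recording edges. With `window` equal to one inter-frame
#' interval this reduces to the raw finite-difference speed.
#'
#' @param track A `cricket_track` with at least two frames.
#' @param window Smoothing window (s); at least `1/fps`.
#' @return Numeric vector of speeds (m/s), one per frame.
#' @export
frame_speeds <- function(track, window = 0.25) {
  stopifnot(inherits(track, "cricket_track"))
  n <- length(track$times)
  if (n < 2L) stop("frame_speeds: track must have at least 2 frames")
  if (window < 1 / track$fps) stop("frame_speeds: window must be at least 1/fps")
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  cs <- c(0, cumsum(steps))
  half <- max(1L, round(window * track$fps / 2))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi] - cs[lo]) / ((hi - lo) / track$fps)
}

#' Segment a track into alternating movement and resting bouts
#'
#' Classifies each frame as moving (smoothed speed strictly above
#' `resting_speed`) or stationary, turns maximal moving runs into candidate
#' movement bouts, absorbs candidates whose path length does not exceed
#' `min_movement_length` into the flanking rests, and merges adjacent rests.
#' Bout boundaries are placed on the last frame of each run, so bout
#' durations always sum exactly to the recording duration. A recording that
#' starts or ends mid-movement keeps the partial bout as movement whenever
#' its path length exceeds the threshold.
#'
#' @param track A `cricket_track`.
#' @param th A [thresholds()] object.
#' @return A `bout_seq`: data frame with columns kind
#'   ("movement"/"resting"), start_time, end_time, duration, path_length, and
#'   attributes `total_duration`, `cricket_id`, `day`.
#' @export
segment_bouts <- function(track, th = thresholds()) {
  stopifnot(inherits(track, "cricket_track"), inherits(th, "seg_thresholds"))
  n <- length(track$times)
  total_dur <- track$times[n] - track$times[1]
  if (n < 2L || total_dur < th$speed_window)
    stop("segment_bouts: track shorter than one smoothing window")
  speeds <- frame_speeds(track, th$speed_window)
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  cs <- c(0, cumsum(steps))

  moving <- speeds > th$resting_speed
  r <- rle(moving)
  ends <- cumsum(r$lengths)               # frame index of each run's last frame
  K <- length(ends)
  ends[K] <- n                            # final boundary is the last frame
  prev_ends <- c(1L, ends[-K])
  kind <- ifelse(r$values, "movement", "resting")
  start_time <- track$times[prev_ends]
  end_time <- track$times[ends]
  path <- cs[ends] - cs[prev_ends]

  # absorb sub-threshold movement candidates into rest (strict inequality:
  # a bout at exactly the minimum length counts as rest)
  kind[kind == "movement" & path <= th$min_movement_length] <- "resting"

  # merge adjacent bouts of equal kind
  grp <- cumsum(c(TRUE, kind[-1] != kind[-length(kind)]))
  out <- data.frame(
    kind = kind[!duplicated(grp)],
    start_time = start_time[!duplicated(grp)],
    end_time = as.vector(tapply(end_time, grp, function(v) v[length(v)])),
    path_length = as.vector(tapply(path, grp, sum)),
    stringsAsFactors = FALSE)
  out$duration <- out$end_time - out$start_time
  out <- out[out$duration > 0, c("kind", "start_time", "end_time", "duration", "path_length")]
  rownames(out) <- NULL
  structure(out, class = c("bout_seq", "data.frame"),
            total_duration = total_dur,
            cricket_id = track$cricket_id, day = track$day)
}

#' @export
print.bout_seq <- function(x, ...) {
  cat(sprintf("<bout_seq> %s day %s: %d bouts over %.1f s (%d movements)\n",
              attr(x, "cricket_id"), attr(x, "day"), nrow(x),
              attr(x, "total_duration"), sum(x$kind == "movement")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Bout table for a set of tracks
#'
#' @param tracks A `track_set`.
#' @param th A [thresholds()] object.
#' @return Data frame with columns cricket_id, day, kind, start_s, end_s,
#'   duration_s, path_length_m.
#' @export
bout_table <- function(tracks, th = thresholds()) {
  do.call(rbind, lapply(tracks, function(t) {
    b <- segment_bouts(t, th)
    data.frame(cricket_id = t$cricket_id, day = t$day, kind = b$kind,
               start_s = b$start_time, end_s = b$end_time,
               duration_s = b$duration, path_length_m = b$path_length,
               stringsAsFactors = FALSE)
  }))
}
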